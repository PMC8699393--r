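# Shared fixtures and independent oracles.

# A small hand-built co-culture forest with values chosen for hand
# calculation:
#   A  (gen 0): fluor 10, 15, 21 at 0/4/8 h; divides at 9 h
#   A1 (gen 1): fluor 5, 6 at 12/16 h; incomplete at 16.5 h
#   A2 (gen 1): fluor 7 at 12 h; apoptosis at 13 h
#   B  (gen 0): fluor 30, 32 at 0/4 h; incomplete at 5 h
# Reference (first-frame, gen 0) median = median(10, 30) = 20, so the
# normalization factor is 5.  Normalized Fa: A 105, B 160, A1 30, A2 35;
# Fmc: A1 82.5, A2 87.5.
make_toy_forest <- function() {
  cells <- data.frame(
    cell_id = c("A", "A1", "A2", "B"),
    cell_type = "SAOS-2", condition = "co-culture",
    generation = c(0L, 1L, 1L, 0L),
    parent_id = c(NA, "A", "A", NA),
    birth_time_h = c(NA, 9, 9, NA),
    end_time_h = c(9, 16.5, 13, 5),
    fate = c("divided", "incomplete", "apoptosis", "incomplete"),
    stringsAsFactors = FALSE)
  ob <- function(id, t, x, y, fl = NA_real_, kind = "centroid-only")
    data.frame(cell_id = id, time_h = t, x_um = x, y_um = y,
               area_um2 = NA_real_, perimeter_um = NA_real_,
               circularity = NA_real_, fluor = fl, frame_kind = kind,
               stringsAsFactors = FALSE)
  obs <- rbind(
    ob("A", 0, 0, 0, 10, "fluorescence"),
    ob("A", 2, 3, 4),
    ob("A", 4, 6, 8, 15, "fluorescence"),
    ob("A", 6, 9, 12),
    ob("A", 8, 12, 16, 21, "fluorescence"),
    ob("A", 9, 13, 16, kind = "phase"),
    ob("A1", 10, 13, 16),
    ob("A1", 12, 16, 20, 5, "fluorescence"),
    ob("A1", 14, 19, 24),
    ob("A1", 16, 22, 28, 6, "fluorescence"),
    ob("A1", 16.5, 23, 28, kind = "phase"),
    ob("A2", 10, 13, 16),
    ob("A2", 12, 10, 12, 7, "fluorescence"),
    ob("A2", 13, 9, 12, kind = "phase"),
    ob("B", 0, 100, 100, 30, "fluorescence"),
    ob("B", 2, 103, 104),
    ob("B", 4, 106, 108, 32, "fluorescence"),
    ob("B", 5, 107, 108, kind = "phase"))
  lineage_forest("t", cells, obs, duration_days = 2)
}

# O(n^2) brute-force Kendall tau-b: enumerate all pairs, count concordant
# minus discordant, normalize by the tie-corrected denominator.
brute_force_tau <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      S <- S + sign(x[i] - x[j]) * sign(y[i] - y[j])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  S / sqrt((n0 - n1) * (n0 - n2))
}

# Brute-force mean velocity: summed hypotenuses over elapsed days.
brute_force_velocity <- function(path) {
  d <- 0
  for (i in 2:nrow(path))
    d <- d + sqrt((path$x_um[i] - path$x_um[i - 1])^2 +
                  (path$y_um[i] - path$y_um[i - 1])^2)
  d / ((path$time_h[nrow(path)] - path$time_h[1]) / 24)
}

# Filled digital disk mask (pixel centres within radius r of the centre).
disk_mask <- function(r, pad = 2) {
  n <- 2 * (r + pad) + 1
  cx <- r + pad + 1
  xs <- matrix(rep(seq_len(n), n), nrow = n)
  ys <- t(xs)
  (xs - cx)^2 + (ys - cx)^2 <= r^2
}
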