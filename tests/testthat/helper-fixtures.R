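# shared fixture builders and independent oracles

# long landmark tibble from an 11 x 3 coordinate matrix (rows in
# pelvic_landmarks() order)
lm_tbl <- function(coords, specimen_id = "s1", observer_id = "obs1",
                   replicate_id = 1L) {
  tibble::tibble(
    specimen_id = specimen_id, observer_id = observer_id,
    replicate_id = replicate_id,
    landmark = pelvic_landmarks(),
    x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3]
  )
}

# a fixed, clearly non-degenerate landmark configuration (mm)
base_coords <- function() {
  m <- rbind(
    c(-50, 0, 0), c(50, 0, 0),          # ischial spines
    c(-55, 10, -20), c(55, 10, -20),    # ischial tuberosities
    c(0, 60, 80), c(0, 55, 30), c(0, 50, 0),   # promontory, S4/S5, S5 apex
    c(0, 115, 60), c(0, 110, 5),        # dorsal sup / inf symphysis
    c(-62, 20, 40), c(62, 20, 40)       # max iliopectineal
  )
  rownames(m) <- pelvic_landmarks()
  m
}

# random non-degenerate configuration: jittered base
random_coords <- function() {
  base_coords() + matrix(stats::rnorm(33, sd = 8), 11, 3)
}

random_rigid <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rot = q, shift = stats::runif(3, -200, 200))
}

apply_rigid <- function(coords, rigid) {
  sweep(coords %*% t(rigid$rot), 2, -rigid$shift)
}

# independent vector-geometry oracle: angle at vertex p between q and r
angle_at_vertex <- function(p, q, r) {
  u <- q - p; v <- r - p
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# independent ICC oracle: variance components via base aov() sums of squares
icc_a1_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(
    value = as.vector(x),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
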