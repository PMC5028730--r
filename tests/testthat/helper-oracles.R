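# Independent oracles and small fixture builders used across the suite.

# DFT evaluated directly from the definition: X_k = sum_n x_n e^(-2*pi*i*k*n/N)
dense_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1L)) / n)), complex(1))
}

# from-definition main-frequency extraction over bins 1..floor(N/2)
oracle_main_freq <- function(x, frame_rate) {
  spec <- dense_dft(x)
  half <- length(x) %/% 2L
  mags <- Mod(spec[2:(half + 1L)])
  k <- which.max(mags)
  c(freq = k * frame_rate / length(x), phase = Arg(spec[k + 1L]))
}

# explicit-loop 5-tap convolution with 2-sample mirror padding
oracle_conv5 <- function(x, kernel) {
  n <- length(x)
  pad <- c(x[3], x[2], x, x[n - 1], x[n - 2])
  out <- numeric(n)
  for (t in seq_len(n))
    out[t] <- sum(kernel * pad[t:(t + 4)])
  out
}

# a small valid gait record with arbitrary finite coordinates
make_test_record <- function(n = 10L, seed = 1L, subject = "S01",
                             condition = "neutral", camera = "K1") {
  set.seed(seed)
  coords <- matrix(rnorm(n * 75L), n, 75L,
                   dimnames = list(NULL, emogait:::coord_columns(kinect_joints())))
  gait_record(coords, subject, condition, camera)
}

# synthetic SpineBase depth track wrapped into a differenced motion matrix,
# for exercising segmentation in isolation
matrix_from_track <- function(z) {
  n <- length(z)
  coords <- matrix(0, n, 75L,
                   dimnames = list(NULL, emogait:::coord_columns(kinect_joints())))
  coords[, "SpineBase_z"] <- z
  rec <- gait_record(coords, "S01", "neutral")
  differentiate(gauss_smooth(to_body_frame(select_joints(rec))))
}

# a two-class feature table of well-separated Gaussians
make_gaussian_table <- function(n_per_class = 59L, p = 20L, sep = 5,
                                seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, mean = 0), n_per_class, p),
             matrix(rnorm(n_per_class * p, mean = sep), n_per_class, p))
  colnames(x) <- paste0("f", seq_len(p))
  n <- 2L * n_per_class
  feature_table(x,
                data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                           condition = rep(c("a", "b"), each = n_per_class),
                           camera_id = "K1", stringsAsFactors = FALSE))
}
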