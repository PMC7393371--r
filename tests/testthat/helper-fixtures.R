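# Shared fixture builders for the test suite.

# Hand-scored pair log with known trait values:
#   latency 100 s; durations 50, 70, 45 (mean 55); intervals 150, 130
#   (mean 140); suck delays 10, 10 (mean 10); suck durations 15, 20
#   (mean 17.5); third copulation without a suck.
fixture_pair_log <- function(record_id = "pair_001",
                             pairing_type = "lignano") {
  ev <- tibble::tribble(
    ~event_kind,  ~start_s, ~end_s,
    "copulation", 100L,     150L,
    "suck",       160L,     175L,
    "copulation", 300L,     370L,
    "suck",       380L,     400L,
    "copulation", 500L,     545L
  )
  dplyr::mutate(
    ev,
    record_id = record_id, record_kind = "pair",
    pairing_type = pairing_type,
    actor_a = paste0(record_id, "_a"),
    actor_b = ifelse(ev$event_kind == "copulation",
                     paste0(record_id, "_b"), NA_character_),
    copulation_type = NA_character_,
    preceding_copulation_index = NA_integer_
  ) |>
    dplyr::select("record_id", "record_kind", "pairing_type", "event_kind",
                  "actor_a", "actor_b", "start_s", "end_s",
                  "copulation_type", "preceding_copulation_index")
}

# A drop log from a vector of copulation types, sequential and
# non-overlapping, with actors consistent with each type.
fixture_drop_log <- function(drop_id, types, start0 = 10L, dur = 60L,
                             gap = 30L) {
  actors <- list(LL = c("L1", "L2"), LJ = c("L1", "J1"),
                 JJ = c("J1", "J2"))
  n <- length(types)
  starts <- start0 + (seq_len(n) - 1L) * (dur + gap)
  tibble::tibble(
    record_id = drop_id, record_kind = "drop",
    pairing_type = NA_character_, event_kind = "copulation",
    actor_a = paste0(drop_id, "_",
                     vapply(types, function(t) actors[[t]][1], "")),
    actor_b = paste0(drop_id, "_",
                     vapply(types, function(t) actors[[t]][2], "")),
    start_s = as.integer(starts), end_s = as.integer(starts + dur),
    copulation_type = types,
    preceding_copulation_index = NA_integer_
  )
}

# 68-drop metadata table with the experiment's exclusion pattern:
# 5 injured, 4 dim lighting, 59 analysable.
fixture_drop_meta <- function() {
  tibble::tibble(
    drop_id = sprintf("drop_%02d", 1:68),
    excluded = c(rep(1L, 9), rep(0L, 59)),
    exclusion_reason = c(rep("injured worm", 5), rep("dim lighting", 4),
                         rep(NA_character_, 59))
  )
}

# Deterministic 59-drop copulation-type counts, all with m_T > 0.
fixture_drop_counts <- function(n_drops = 59L) {
  i <- seq_len(n_drops)
  tibble::tibble(
    drop_id = sprintf("drop_%02d", i),
    m_LL = 2L + (i %% 4L),
    m_LJ = 1L + (i %% 5L),
    m_JJ = 1L + (i %% 3L)
  ) |>
    dplyr::mutate(m_T = m_LL + m_LJ + m_JJ)
}

# Small asymmetric "stylet-like" outline on an even landmark count,
# compatible with stylet_landmark_scheme(p).
fixture_shape <- function(p = 12L) {
  h <- p / 2
  t <- seq(0, 1, length.out = h)
  top <- cbind(t, 0.25 * sin(pi * t) + 0.1 * t^2 + 0.02)
  bottom <- cbind(rev(t), -0.15 * sin(pi * rev(t)) - 0.02 * rev(t) - 0.03)
  rbind(top, bottom)
}

# n noisy copies of a base shape as a p x 2 x n array.
fixture_shapes <- function(n = 6L, p = 12L, noise_sd = 0.01, seed = 42L) {
  set.seed(seed)
  base <- fixture_shape(p)
  arr <- array(NA_real_, dim = c(p, 2, n),
               dimnames = list(NULL, c("x", "y"), paste0("spec", seq_len(n))))
  for (i in seq_len(n)) {
    arr[, , i] <- base + matrix(rnorm(2 * p, sd = noise_sd), ncol = 2)
  }
  arr
}

# Apply a random similarity transform (rotation + scale + translation,
# no reflection) to a p x 2 configuration.
random_similarity <- function(m, seed) {
  set.seed(seed)
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s <- runif(1, 0.25, 4)
  tr <- runif(2, -5, 5)
  sweep(s * m %*% R, 2, tr, "+")
}
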