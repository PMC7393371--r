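#' Simulation parameters for the synthetic generators
#'
#' Bundles every knob of the synthetic-data generators. The defaults
#' emulate the study conditions: 57 pairs per pairing type observed for
#' 2 h at 1 frame/s; *M. janickei* copulations about five-fold longer and
#' about half as frequent as *M. lignano*; heterospecific pairs mixing the
#' two species' behaviour with inflated variance and rare sucks;
#' hybrid offspring in roughly a fifth of heterospecific pairs, and never
#' from both partners of a pair; 59 mate-choice drops of 2+2 individuals;
#' stylet samples of 25 *M. lignano*, 29 hybrids and 18 *M. janickei*,
#' with the hybrid mean shape midway between the aligned species means
#' and a somewhat larger centroid size. Log-scale standard deviations are
#' set so the back-transformed CVs reproduce the qualitative pattern that
#' heterospecific pairs are the most variable.
#'
#' @param seed Integer master seed; each generator draws from its own
#'   substream (`seed + 1` pair logs, `seed + 2` drops, `seed + 3`
#'   stylets) so datasets can be regenerated independently.
#' @param n_pairs Pairs per pairing type.
#' @param window_s Observation window in seconds (2 h at 1 frame/s).
#' @param behaviour Per-species log-normal behaviour parameters (medians
#'   in seconds via `meanlog`, spreads via `sdlog`) and per-copulation
#'   suck probabilities; see the default for the structure.
#' @param hetero_sd_inflation Multiplier on log-sds in heterospecific
#'   pairs (their behaviour is less stereotyped).
#' @param hetero_latency_factor Multiplier on the heterospecific latency
#'   median (heterospecific pairs start mating latest).
#' @param hetero_suck_prob Per-copulation suck probability in
#'   heterospecific pairs (sucks are rare there).
#' @param fecundity Offspring-count model: conspecific Poisson means and
#'   the heterospecific success probability / offspring mean (at most one
#'   maternal individual of a heterospecific pair is productive).
#' @param n_drops Number of mate-choice drops.
#' @param propensity_L,propensity_J Relative per-individual mating
#'   propensities.
#' @param preference Conspecific preference multiplier on the pair hazard
#'   (1 = random mating).
#' @param base_rate_per_hour Copulation hazard (per hour) of a pair of
#'   two propensity-1 individuals, anchoring the absolute time scale.
#' @param stylet Stylet-shape generator settings: group sizes, hybrid
#'   interpolation weight, hybrid size multiplier, isotropic landmark
#'   noise sd (shape units; mean shapes have centroid size ~1).
#'
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(
    seed = 1L,
    n_pairs = 57L,
    window_s = 7200L,
    behaviour = list(
      lignano = list(latency_meanlog = log(400), latency_sdlog = 0.744,
                     duration_meanlog = log(60), duration_sdlog = 0.265,
                     interval_meanlog = log(500), interval_sdlog = 0.833,
                     suck_delay_meanlog = log(2), suck_delay_sdlog = 1.356,
                     suck_duration_meanlog = log(15),
                     suck_duration_sdlog = 0.208,
                     suck_prob = 0.8),
      janickei = list(latency_meanlog = log(600), latency_sdlog = 0.980,
                      duration_meanlog = log(300), duration_sdlog = 0.376,
                      interval_meanlog = log(1100), interval_sdlog = 0.624,
                      suck_delay_meanlog = log(60), suck_delay_sdlog = 1.184,
                      suck_duration_meanlog = log(25),
                      suck_duration_sdlog = 0.159,
                      suck_prob = 0.5)
    ),
    hetero_sd_inflation = 1.3,
    hetero_latency_factor = 1.5,
    hetero_suck_prob = 0.15,
    fecundity = list(conspecific_mean = 15,
                     hetero_success_prob = 0.2,
                     hetero_mean = 4),
    n_drops = 59L,
    propensity_L = 1,
    propensity_J = 0.5,
    preference = 1,
    base_rate_per_hour = 6,
    stylet = list(n = c(lignano = 25L, hybrid = 29L, janickei = 18L),
                  hybrid_weight = 0.5,
                  hybrid_size = 1.15,
                  noise_sd = 0.01)) {
  stopifnot(propensity_L >= 0, propensity_J >= 0, preference > 0,
            stylet$hybrid_weight >= 0, stylet$hybrid_weight <= 1,
            stylet$noise_sd >= 0, window_s > 0)
  structure(as.list(environment()), class = "sim_params")
}

#' Read simulation parameters from a YAML config file
#'
#' The file mirrors the [sim_params()] argument structure (nested
#' sections for `behaviour`, `fecundity`, `stylet`); keys not present
#' keep their defaults. Nested sections are merged key-wise.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed override.
#' @return A `"sim_params"` object.
#' @export
read_sim_config <- function(path, seed = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading config files requires the yaml package")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(seed)) cfg$seed <- seed
  defaults <- formals(sim_params)
  base <- sim_params()
  for (nm in names(cfg)) {
    if (!nm %in% names(defaults)) abort(paste0("unknown config key: ", nm))
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      utils::modifyList(base[[nm]], cfg[[nm]])
    } else {
      cfg[[nm]]
    }
  }
  do.call(sim_params, base[names(defaults)])
}

# Effective behaviour parameters for a pairing type: heterospecific pairs
# mix the species' log-means and inflate the log-sds.
.pairing_behaviour <- function(params, pairing_type) {
  b <- params$behaviour
  if (pairing_type == "lignano") return(b$lignano)
  if (pairing_type == "janickei") return(b$janickei)
  mix <- purrr::map2(b$lignano, b$janickei, ~ mean(c(.x, .y)))
  for (nm in grep("_sdlog$", names(mix), value = TRUE)) {
    mix[[nm]] <- mix[[nm]] * params$hetero_sd_inflation
  }
  mix$latency_meanlog <- mix$latency_meanlog +
    log(params$hetero_latency_factor)
  mix$suck_prob <- params$hetero_suck_prob
  mix
}

#' Simulate scored pair logs
#'
#' Generates frame-scored (integer-second) event logs for conspecific and
#' heterospecific mating pairs: log-normal copulation latency, durations
#' and intervals per pairing type, truncated at the 2-h window; after each
#' copulation a suck is inserted with the pairing type's probability,
#' delayed and sized log-normally, and clipped so it never overlaps the
#' next copulation. Output is accepted unchanged by
#' [validate_event_log()] and [extract_traits()].
#'
#' @param params A [sim_params()] object.
#' @param pairing_types Which pairing types to generate.
#' @param n Pairs per pairing type (default `params$n_pairs`).
#' @param seed Seed (default the pair-log substream of `params$seed`).
#' @return A pair-schema event tibble (see [read_event_log()]).
#' @export
sim_pair_logs <- function(params = sim_params(),
                          pairing_types = PAIRING_TYPES,
                          n = params$n_pairs, seed = params$seed + 1L) {
  set.seed(seed)
  W <- params$window_s
  rows <- list()
  for (pt in pairing_types) {
    b <- .pairing_behaviour(params, pt)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", pt, i)
      t <- round(rlnorm(1, b$latency_meanlog, b$latency_sdlog))
      cop_idx <- 0L
      pend_suck <- NULL
      while (t < W) {
        dur <- max(5, round(rlnorm(1, b$duration_meanlog, b$duration_sdlog)))
        end <- t + dur
        if (end > W) {
          if (W - t >= 5) end <- W else break
        }
        cop_idx <- cop_idx + 1L
        if (!is.null(pend_suck)) {
          # clip the previous copulation's suck at this copulation's start
          s <- pend_suck
          s$end_s <- min(s$end_s, t)
          if (s$start_s < t && s$end_s > s$start_s) {
            rows[[length(rows) + 1L]] <- s
          }
          pend_suck <- NULL
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          record_id = id, record_kind = "pair", pairing_type = pt,
          event_kind = "copulation", actor_a = paste0(id, "_a"),
          actor_b = paste0(id, "_b"), start_s = t, end_s = end,
          copulation_type = NA_character_,
          preceding_copulation_index = NA_integer_
        )
        if (runif(1) < b$suck_prob) {
          s_start <- end + round(rlnorm(1, b$suck_delay_meanlog,
                                        b$suck_delay_sdlog))
          s_end <- s_start + max(1, round(rlnorm(1, b$suck_duration_meanlog,
                                                 b$suck_duration_sdlog)))
          if (s_start < W) {
            pend_suck <- tibble::tibble(
              record_id = id, record_kind = "pair", pairing_type = pt,
              event_kind = "suck", actor_a = paste0(id, "_a"),
              actor_b = NA_character_, start_s = s_start,
              end_s = min(s_end, W), copulation_type = NA_character_,
              preceding_copulation_index = cop_idx
            )
          }
        }
        if (end >= W) break
        t <- end + max(1, round(rlnorm(1, b$interval_meanlog,
                                       b$interval_sdlog)))
      }
      if (!is.null(pend_suck) && pend_suck$end_s > pend_suck$start_s) {
        rows[[length(rows) + 1L]] <- pend_suck
      }
    }
  }
  ev <- dplyr::bind_rows(rows)
  ev$start_s <- as.integer(ev$start_s)
  ev$end_s <- as.integer(ev$end_s)
  validate_event_log(ev, schema = "pair", window_s = W)
}

#' Simulate post-pairing fecundity
#'
#' Offspring counts of the isolated maternal individuals over the 14-day
#' window: one maternal individual per conspecific pair (Poisson with the
#' conspecific mean), both individuals of each heterospecific pair, of
#' which at most one is productive — a heterospecific pair succeeds with
#' `fecundity$hetero_success_prob` and the productive parent is drawn at
#' random.
#'
#' @inheritParams sim_pair_logs
#' @return A tibble `record_id`, `pairing_type`, `maternal_id`,
#'   `n_offspring`, joinable to [extract_traits()] via
#'   the `offspring` argument.
#' @export
sim_fecundity <- function(params = sim_params(),
                          pairing_types = PAIRING_TYPES,
                          n = params$n_pairs, seed = params$seed + 4L) {
  set.seed(seed)
  fec <- params$fecundity
  rows <- list()
  for (pt in pairing_types) {
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", pt, i)
      if (pt == "hetero") {
        success <- runif(1) < fec$hetero_success_prob
        counts <- c(0L, 0L)
        if (success) {
          counts[sample(2, 1)] <- 1L + rpois(1, fec$hetero_mean - 1)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          record_id = id, pairing_type = pt,
          maternal_id = paste0(id, c("_a", "_b")), n_offspring = counts
        )
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          record_id = id, pairing_type = pt,
          maternal_id = paste0(id, "_a"),
          n_offspring = rpois(1, fec$conspecific_mean)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate mate-choice drops
#'
#' Each drop holds two *M. lignano* (`L1`, `L2`) and two *M. janickei*
#' (`J1`, `J2`), giving six candidate dyads (1 LL, 4 LJ, 1 JJ). Dyads
#' copulate under competing exponential clocks with hazard proportional
#' to `propensity_i * propensity_j`, multiplied by `preference` for
#' conspecific dyads; individuals are unavailable for the duration of
#' their own copulation. Random mating is modelled at the species level:
#' each participation of a copulation is an independent propensity-
#' weighted species draw (a Hardy-Weinberg encounter process), so the
#' four heterospecific dyads share the heterospecific hazard `2 p q` and
#' each carries half the per-dyad weight of a conspecific dyad. With
#' equal propensities and `preference = 1` the first copulation is then
#' LL : LJ : JJ = 0.25 : 0.50 : 0.25, the random-mating null, and the
#' mating rate `p` recovers
#' `propensity_L / (propensity_L + propensity_J)`.
#'
#' @inheritParams sim_pair_logs
#' @param n_drops Number of drops (default `params$n_drops`).
#' @param max_events Stop each drop after this many copulations (default
#'   unlimited; `1` simulates first copulations only).
#' @return A drop-schema event tibble with typed copulations.
#' @export
sim_drops <- function(params = sim_params(), n_drops = params$n_drops,
                      max_events = Inf, seed = params$seed + 2L) {
  set.seed(seed)
  W <- params$window_s
  base <- params$base_rate_per_hour / 3600
  prop <- c(L1 = params$propensity_L, L2 = params$propensity_L,
            J1 = params$propensity_J, J2 = params$propensity_J)
  pairs <- rbind(
    c("L1", "L2"), c("L1", "J1"), c("L1", "J2"),
    c("L2", "J1"), c("L2", "J2"), c("J1", "J2")
  )
  ptype <- c("LL", "LJ", "LJ", "LJ", "LJ", "JJ")
  pref <- ifelse(ptype == "LJ", 1, params$preference)
  # Hardy-Weinberg weighting: the heterospecific category hazard 2pq is
  # shared by its four dyads, conspecific p^2 / q^2 by one dyad each
  mult <- ifelse(ptype == "LJ", 0.5, 1)
  rate <- base * prop[pairs[, 1]] * prop[pairs[, 2]] * pref * mult
  ia <- match(pairs[, 1], names(prop))
  ib <- match(pairs[, 2], names(prop))
  dur_par <- list(
    LL = .pairing_behaviour(params, "lignano"),
    LJ = .pairing_behaviour(params, "hetero"),
    JJ = .pairing_behaviour(params, "janickei")
  )

  out <- vector("list", n_drops)
  for (d in seq_len(n_drops)) {
    busy <- numeric(4)
    t <- 0
    ev_start <- integer(0)
    ev_end <- integer(0)
    ev_pair <- integer(0)
    while (t < W && length(ev_start) < max_events) {
      free <- busy <= t
      avail <- free[ia] & free[ib]
      if (!any(avail)) {
        t <- min(busy[busy > t])
        next
      }
      r <- rate[avail]
      total <- sum(r)
      if (total <= 0) {
        # only zero-hazard pairs available; wait for the next release
        if (!any(busy > t)) break
        t <- min(busy[busy > t])
        next
      }
      cap <- min(c(busy[busy > t], W))
      t_new <- t + stats::rexp(1, total)
      if (t_new >= cap) {
        t <- cap
        next
      }
      t <- t_new
      k <- which(avail)[sample.int(sum(avail), 1, prob = r)]
      bp <- dur_par[[ptype[k]]]
      dur <- max(5, round(rlnorm(1, bp$duration_meanlog, bp$duration_sdlog)))
      start_i <- floor(t)
      end_i <- start_i + dur
      if (end_i > W) {
        if (W - start_i >= 5) end_i <- W else break
      }
      ev_start <- c(ev_start, start_i)
      ev_end <- c(ev_end, end_i)
      ev_pair <- c(ev_pair, k)
      busy[c(ia[k], ib[k])] <- end_i
      t <- t_new
    }
    if (length(ev_start) > 0) {
      out[[d]] <- tibble::tibble(
        record_id = sprintf("drop_%04d", d), record_kind = "drop",
        pairing_type = NA_character_, event_kind = "copulation",
        actor_a = paste0("drop_", d, "_", pairs[ev_pair, 1]),
        actor_b = paste0("drop_", d, "_", pairs[ev_pair, 2]),
        start_s = as.integer(ev_start), end_s = as.integer(ev_end),
        copulation_type = ptype[ev_pair],
        preceding_copulation_index = NA_integer_
      )
    } else {
      out[[d]] <- tibble::tibble(
        record_id = sprintf("drop_%04d", d), record_kind = "drop",
        pairing_type = NA_character_, event_kind = character(0),
        actor_a = character(0), actor_b = character(0),
        start_s = integer(0), end_s = integer(0),
        copulation_type = character(0),
        preceding_copulation_index = integer(0)
      )
    }
  }
  ev <- dplyr::bind_rows(out)
  validate_event_log(ev, schema = "drop", window_s = W)
}

#' Default species mean stylet shapes
#'
#' Two synthetic 60-point stylet outlines on the standard landmark scheme
#' ([stylet_landmark_scheme()]): a gradually narrowing funnel with a
#' gentle (~40 degree) total curvature for *M. lignano*, and a funnel
#' whose tip adds a sharp (>90 degree) hook for *M. janickei*. They are
#' synthetic fixtures qualitatively matching the two species' stylet
#' geometry, not tracings of any specimen. Both have centroid size ~1.
#'
#' @return A list of two `60 x 2` matrices, `lignano` and `janickei`.
#' @export
default_stylet_shapes <- function() {
  outline <- function(hook) {
    m <- 400 # fine polyline, resampled to equal spacing below
    tt <- seq(0, 1, length.out = m)
    theta <- 0.7 * tt
    if (hook > 0) theta <- theta + hook * pmax(0, (tt - 0.7) / 0.3)^2
    ds <- 1 / (m - 1)
    cx <- cumsum(c(0, cos(theta[-1]) * ds))
    cy <- cumsum(c(0, sin(theta[-1]) * ds))
    wd <- 0.12 * (1 - 0.85 * tt) + 0.018
    nx <- -sin(theta)
    ny <- cos(theta)
    resample <- function(px, py, k) {
      s <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
      si <- seq(0, s[length(s)], length.out = k)
      cbind(stats::approx(s, px, si)$y, stats::approx(s, py, si)$y)
    }
    far <- resample(cx + nx * wd, cy + ny * wd, 30) # base -> tip
    near <- resample(cx - nx * wd, cy - ny * wd, 30)
    pts <- rbind(far, near[30:1, ]) # 31-60 run tip -> base
    pts <- sweep(pts, 2, colMeans(pts))
    pts / sqrt(sum(pts^2))
  }
  list(lignano = outline(0), janickei = outline(2.0))
}

#' Simulate stylet landmark configurations
#'
#' Draws specimens around group mean shapes: the two species means from
#' [default_stylet_shapes()] (or supplied via `params$stylet$means`), and
#' a hybrid mean obtained by Procrustes-aligning the species means,
#' interpolating linearly at `hybrid_weight`, and scaling by
#' `hybrid_size`. Isotropic Gaussian noise of sd `noise_sd` is added to
#' every landmark coordinate.
#'
#' @inheritParams sim_pair_logs
#' @param seed Seed (default the stylet substream of `params$seed`).
#' @return A landmark tibble (`specimen_id`, `group`, `landmark`, `x`,
#'   `y`, `fixed`, `curve`, `mirrored`) ready for [gpa_align()].
#' @export
sim_stylets <- function(params = sim_params(), seed = params$seed + 3L) {
  set.seed(seed)
  st <- params$stylet
  means <- if (!is.null(st$means)) st$means else default_stylet_shapes()
  fit <- gpa_align(array(c(means$lignano, means$janickei),
                         dim = c(nrow(means$lignano), 2, 2)))
  aligned_L <- fit$aligned[, , 1]
  aligned_J <- fit$aligned[, , 2]
  w <- st$hybrid_weight
  hybrid <- ((1 - w) * aligned_L + w * aligned_J) * st$hybrid_size
  group_means <- list(lignano = aligned_L, hybrid = hybrid,
                      janickei = aligned_J)
  scheme <- stylet_landmark_scheme(nrow(aligned_L))

  rows <- list()
  for (g in names(st$n)) {
    for (i in seq_len(st$n[[g]])) {
      pts <- group_means[[g]] +
        matrix(rnorm(length(group_means[[g]]), sd = st$noise_sd),
               ncol = 2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        specimen_id = sprintf("%s_%03d", g, i), group = g,
        landmark = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2],
        fixed = seq_len(nrow(pts)) %in% scheme$fixed,
        curve = ifelse(seq_len(nrow(pts)) <= nrow(pts) / 2, "far", "near"),
        mirrored = FALSE
      )
    }
  }
  dplyr::bind_rows(rows)
}
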