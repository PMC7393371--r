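#' The 60-landmark stylet digitisation scheme
#'
#' Each stylet carries 60 ordered 2-D landmarks: two fixed landmarks each
#' on the tip and base (ordinals 1, 30, 31, 60) and 28 sliding
#' semilandmarks along each curved side. Ordinals 1-30 trace the side
#' further from the seminal vesicle, 31-60 the nearer side. Ordinals are
#' 1-based in all user-facing I/O.
#'
#' @param p Number of landmarks (the scheme generalises only in tests;
#'   default 60).
#' @return A list with `fixed` (ordinals of fixed landmarks) and `curves`
#'   (list of ordinal vectors, one per curve, endpoints fixed).
#' @export
stylet_landmark_scheme <- function(p = 60L) {
  stopifnot(p %% 2 == 0, p >= 6)
  h <- p %/% 2
  list(fixed = c(1L, h, h + 1L, p),
       curves = list(far = seq_len(h), near = (h + 1L):p))
}

#' Convert a long landmark tibble to a p x 2 x n array
#'
#' @param landmarks Tibble with `specimen_id`, `landmark`, `x`, `y` (and
#'   optionally `group`). Landmarks must be complete and consistently
#'   numbered across specimens.
#' @return A `p x 2 x n` array, specimens in order of first appearance,
#'   with a `groups` attribute when a `group` column is present.
#' @export
landmarks_to_array <- function(landmarks) {
  lm <- tibble::as_tibble(landmarks)
  ids <- unique(lm$specimen_id)
  ords <- sort(unique(lm$landmark))
  p <- length(ords)
  arr <- array(NA_real_, dim = c(p, 2, length(ids)),
               dimnames = list(NULL, c("x", "y"), ids))
  for (i in seq_along(ids)) {
    s <- lm[lm$specimen_id == ids[i], , drop = FALSE]
    if (nrow(s) != p || !all(sort(s$landmark) == ords)) {
      abort(paste0("specimen ", ids[i], " does not carry all ", p,
                   " landmarks"))
    }
    s <- s[order(s$landmark), , drop = FALSE]
    arr[, , i] <- cbind(s$x, s$y)
  }
  if ("group" %in% names(lm)) {
    grp <- lm |>
      dplyr::distinct(.data$specimen_id, .data$group)
    attr(arr, "groups") <- setNames(grp$group, grp$specimen_id)[ids]
  }
  arr
}

#' Convert a p x 2 x n array back to a long landmark tibble
#'
#' @param arr A `p x 2 x n` landmark array (see [landmarks_to_array()]).
#' @param groups Optional character vector of group labels per specimen.
#' @return A tibble with `specimen_id`, `group` (if given), `landmark`,
#'   `x`, `y`.
#' @export
array_to_landmarks <- function(arr, groups = attr(arr, "groups")) {
  p <- dim(arr)[1]
  n <- dim(arr)[3]
  ids <- dimnames(arr)[[3]]
  if (is.null(ids)) ids <- paste0("spec", seq_len(n))
  out <- tibble::tibble(
    specimen_id = rep(ids, each = p),
    landmark = rep(seq_len(p), times = n),
    x = as.vector(arr[, 1, ]),
    y = as.vector(arr[, 2, ])
  )
  if (!is.null(groups)) {
    out <- dplyr::mutate(out, group = rep(unname(groups), each = p),
                         .after = "specimen_id")
  }
  out
}

.as_config_matrix <- function(config) {
  if (is.data.frame(config)) {
    config <- config[order(config$landmark), , drop = FALSE]
    cbind(x = config$x, y = config$y)
  } else {
    as.matrix(config)
  }
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard size measure in geometric morphometrics.
#' Scales linearly with the configuration and is translation invariant.
#'
#' @param config A landmark tibble (one specimen), a `p x 2` matrix, or a
#'   `p x 2 x n` array (vectorised over specimens).
#' @return A numeric size (or vector of sizes for an array).
#' @export
#' @examples
#' centroid_size(rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) # 2 sqrt 2
centroid_size <- function(config) {
  if (is.array(config) && length(dim(config)) == 3) {
    return(apply(config, 3, centroid_size))
  }
  m <- .as_config_matrix(config)
  cs <- sqrt(sum(sweep(m, 2, colMeans(m))^2))
  if (cs == 0) abort("degenerate configuration: all landmarks coincide")
  cs
}

#' Mirror a landmark configuration
#'
#' Negates the x-coordinates while preserving landmark ordering, and
#' toggles the `mirrored` flag if present. Stylets can be imaged from the
#' ventral or dorsal side; mirroring brings all specimens to a common
#' orientation before alignment, since the alignment itself never
#' reflects.
#'
#' @param landmarks A landmark tibble (any number of specimens) or a
#'   `p x 2` matrix.
#' @return Same shape as the input, mirrored.
#' @export
mirror_configuration <- function(landmarks) {
  if (is.data.frame(landmarks)) {
    out <- dplyr::mutate(tibble::as_tibble(landmarks), x = -.data$x)
    if ("mirrored" %in% names(out)) out$mirrored <- !out$mirrored
    out
  } else {
    m <- landmarks
    m[, 1] <- -m[, 1]
    m
  }
}

# Optimal rotation (no reflection) of X onto Y, both centered.
.rotation_to <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 2] <- -u[, 2]
    R <- u %*% t(s$v)
  }
  R
}

.center_scale <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

# Canonical orientation: principal axes of the consensus along the
# coordinate axes, 180-degree ambiguity resolved by the sign of the first
# sufficiently nonzero consensus coordinate.
.canonical_rotation <- function(consensus) {
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  E <- e$vectors
  if (det(E) < 0) E[, 2] <- -E[, 2]
  rot <- consensus %*% E
  v <- as.vector(t(rot))
  lead <- which(abs(v) > 1e-8 * max(abs(v)))[1]
  if (!is.na(lead) && v[lead] < 0) E <- -E
  E
}

#' Generalized Procrustes alignment
#'
#' Iterative superimposition of landmark configurations: each is centered,
#' scaled to unit centroid size, and rotated to minimise its summed
#' squared distance to the consensus; the consensus is the mean of the
#' aligned shapes, re-standardised, and iterated to convergence.
#' Reflections are never allowed — chirality is handled upstream by
#' [mirror_configuration()]. The final consensus is put in a canonical
#' principal-axis orientation so the result does not depend on input
#' order or on similarity transforms of any input.
#'
#' @param landmarks A landmark tibble or a `p x 2 x n` array; at least two
#'   configurations with equal landmark counts.
#' @param tol Convergence tolerance on the consensus change (default
#'   1e-10).
#' @param max_iter Maximum iterations (default 100); non-convergence is an
#'   error reporting the last change.
#' @return An object of class `"gpa_fit"`: `aligned` (`p x 2 x n`, unit
#'   centroid size), `consensus` (`p x 2`, unit centroid size),
#'   `centroid_size` (original sizes), `groups`, `iterations`,
#'   `rss_trace` (summed squared residuals per iteration).
#' @export
gpa_align <- function(landmarks, tol = 1e-10, max_iter = 100L) {
  arr <- if (is.data.frame(landmarks)) landmarks_to_array(landmarks) else landmarks
  n <- dim(arr)[3]
  if (is.null(n) || n < 2) abort("need at least two configurations")
  csize <- apply(arr, 3, centroid_size)
  std <- arr
  for (i in seq_len(n)) std[, , i] <- .center_scale(arr[, , i])

  consensus <- .center_scale(apply(std, c(1, 2), mean))
  rss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      std[, , i] <- std[, , i] %*% .rotation_to(std[, , i], consensus)
    }
    new_consensus <- .center_scale(apply(std, c(1, 2), mean))
    rss_trace <- c(rss_trace,
                   sum(sweep(std, c(1, 2), new_consensus)^2))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) break
  }
  if (delta >= tol) {
    abort(paste0("GPA did not converge in ", max_iter,
                 " iterations (last consensus change ",
                 format(delta), ")"))
  }
  R <- .canonical_rotation(consensus)
  consensus <- consensus %*% R
  for (i in seq_len(n)) std[, , i] <- std[, , i] %*% R
  dimnames(std) <- dimnames(arr)

  structure(
    list(aligned = std, consensus = consensus, centroid_size = csize,
         groups = attr(arr, "groups"), iterations = it,
         rss_trace = rss_trace),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes alignment:", dim(x$aligned)[3], "specimens,",
      dim(x$aligned)[1], "landmarks,", x$iterations, "iterations\n")
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Root summed squared difference after centering, scaling to unit
#' centroid size, and optimal (reflection-free) rotation of `b` onto `a`.
#'
#' @param a,b Landmark matrices or single-specimen tibbles.
#' @return A nonnegative distance.
#' @export
procrustes_distance <- function(a, b) {
  A <- .center_scale(.as_config_matrix(a))
  B <- .center_scale(.as_config_matrix(b))
  B <- B %*% .rotation_to(B, A)
  sqrt(sum((A - B)^2))
}

# Bending energy matrix of a reference configuration (p x p).
.bending_energy_matrix <- function(ref) {
  p <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 == 0, 0, d2 * log(d2)) / 2 # r^2 log r = (r^2 log r^2)/2
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- tryCatch(solve(L), error = function(e)
    abort("singular thin-plate-spline system: degenerate landmarks"))
  Li[seq_len(p), seq_len(p), drop = FALSE]
}

#' Slide semilandmarks along their curves
#'
#' Semilandmarks capture curve shape without point-to-point homology, so
#' each is allowed to slide along its local tangent direction (the chord
#' between its neighbours on the curve) to minimise either the bending
#' energy of its specimen's deformation from the consensus (default, the
#' convention of the tps software family) or the Procrustes distance to
#' the consensus. Fixed landmarks never move. After each sliding pass the
#' configurations are re-aligned by GPA and the consensus updated;
#' iteration stops when the criterion changes by less than `tol` or stops
#' decreasing (the best iterate is kept, so the recorded trace is
#' monotone nonincreasing).
#'
#' @param fit A `"gpa_fit"` from [gpa_align()].
#' @param scheme Landmark scheme (see [stylet_landmark_scheme()]); default
#'   inferred from the landmark count.
#' @param criterion `"bending"` (bending energy) or `"chord"` (Procrustes
#'   distance).
#' @param tol Convergence tolerance on the summed criterion (default
#'   1e-8).
#' @param max_iter Maximum outer sliding iterations (default 20).
#' @return A `"gpa_fit"` with slid, re-aligned shapes plus
#'   `slide_trace` (criterion value per iteration) and
#'   `slide_criterion`.
#' @export
slide_semilandmarks <- function(fit, scheme = NULL,
                                criterion = c("bending", "chord"),
                                tol = 1e-8, max_iter = 20L) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(fit, "gpa_fit"))
  p <- dim(fit$aligned)[1]
  n <- dim(fit$aligned)[3]
  if (is.null(scheme)) scheme <- stylet_landmark_scheme(p)
  sliders <- setdiff(seq_len(p), scheme$fixed)
  # neighbours of each slider within its own curve
  nb <- matrix(NA_integer_, length(sliders), 2)
  for (k in seq_along(sliders)) {
    s <- sliders[k]
    curve <- scheme$curves[[which(purrr::map_lgl(scheme$curves,
                                                 ~ s %in% .x))[1]]]
    pos <- match(s, curve)
    if (pos == 1 || pos == length(curve)) {
      abort(paste0("slider ", s, " sits at a curve endpoint"))
    }
    nb[k, ] <- c(curve[pos - 1], curve[pos + 1])
  }

  arr <- fit$aligned
  consensus <- fit$consensus
  objective <- function(arr, consensus, BE) {
    if (criterion == "chord") {
      sum(sweep(arr, c(1, 2), consensus)^2)
    } else {
      val <- 0
      for (i in seq_len(n)) {
        val <- val + sum(arr[, 1, i] %*% BE %*% arr[, 1, i]) +
          sum(arr[, 2, i] %*% BE %*% arr[, 2, i])
      }
      val
    }
  }

  trace <- numeric(0)
  prev <- Inf
  prev_arr <- arr
  prev_consensus <- consensus
  for (it in seq_len(max_iter)) {
    BE <- if (criterion == "bending") .bending_energy_matrix(consensus) else NULL
    for (i in seq_len(n)) {
      cfg <- arr[, , i]
      tang <- cfg[nb[, 2], , drop = FALSE] - cfg[nb[, 1], , drop = FALSE]
      len <- sqrt(rowSums(tang^2))
      if (any(len < 1e-12)) {
        abort(paste0("degenerate tangent at landmark ",
                     sliders[which(len < 1e-12)[1]],
                     ": coincident neighbours"))
      }
      tang <- tang / len
      if (criterion == "chord") {
        resid <- cfg[sliders, , drop = FALSE] -
          consensus[sliders, , drop = FALSE]
        t_amt <- -rowSums(resid * tang)
      } else {
        m <- length(sliders)
        # U: 2p x m tangent matrix, coordinates stacked (x block, y block)
        U <- matrix(0, 2 * p, m)
        U[cbind(sliders, seq_len(m))] <- tang[, 1]
        U[cbind(p + sliders, seq_len(m))] <- tang[, 2]
        v <- c(cfg[, 1], cfg[, 2])
        cvec <- c(consensus[, 1], consensus[, 2])
        E2U <- rbind(BE %*% U[seq_len(p), ], BE %*% U[p + seq_len(p), ])
        A <- crossprod(U, E2U)
        b <- -crossprod(E2U, v - cvec)
        t_amt <- tryCatch(as.vector(solve(A, b)),
                          error = function(e)
                            as.vector(MASS::ginv(A) %*% b))
      }
      cfg[sliders, ] <- cfg[sliders, , drop = FALSE] + t_amt * tang
      arr[, , i] <- cfg
    }
    refit <- gpa_align(arr)
    arr <- refit$aligned
    consensus <- refit$consensus
    BE_obj <- if (criterion == "bending")
      .bending_energy_matrix(consensus) else NULL
    cur <- objective(arr, consensus, BE_obj)
    if (cur > prev) {
      # the criterion stopped improving (the consensus reference moved
      # against us): keep the best iterate so the trace is monotone
      arr <- prev_arr
      consensus <- prev_consensus
      break
    }
    trace <- c(trace, cur)
    if (abs(prev - cur) < tol) break
    prev <- cur
    prev_arr <- arr
    prev_consensus <- consensus
  }

  out <- fit
  out$aligned <- arr
  out$consensus <- consensus
  out$slide_trace <- trace
  out$slide_criterion <- criterion
  out$iterations <- it
  out
}

#' Relative warps of aligned shapes
#'
#' Decomposes Procrustes shape variation into its major axes. With
#' `alpha = 0` (the default and the only setting under which the first
#' relative warp score, RWS1, is an ordinary principal component) this is
#' a principal-component decomposition of the flattened aligned
#' coordinates. `alpha != 0` reweights the non-affine variation by powers
#' of the bending-energy eigenvalues (positive alpha emphasises
#' large-scale deformation), provided for parity with the tps software
#' family.
#'
#' @param fit A `"gpa_fit"` (optionally after
#'   [slide_semilandmarks()]).
#' @param alpha Bending-energy weighting exponent (default 0).
#' @param tol Relative threshold on singular values below which a warp
#'   counts as zero-variance.
#' @return An object of class `"relative_warps"`: `scores` tibble
#'   (specimen, group, centroid size, RWS1..RWSk over nonzero warps),
#'   `var_explained` (percent per nonzero warp, summing to 100),
#'   `n_warps`, `sdev`, `rotation`, `consensus`, `alpha`.
#' @export
relative_warps <- function(fit, alpha = 0, tol = 1e-6) {
  stopifnot(inherits(fit, "gpa_fit"))
  n <- dim(fit$aligned)[3]
  if (n < 3) abort("need at least 3 specimens for a shape decomposition")
  p <- dim(fit$aligned)[1]
  X <- t(apply(fit$aligned, 3, as.vector)) # n x 2p, (x block, y block)

  if (alpha == 0) {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    sdev <- pc$sdev
    scores <- pc$x
    rotation <- pc$rotation
  } else {
    BE <- .bending_energy_matrix(fit$consensus)
    eb <- eigen(BE, symmetric = TRUE)
    keep <- eb$values > max(eb$values) * 1e-9
    Ev <- eb$vectors[, keep, drop = FALSE]
    lam <- eb$values[keep]
    # principal-warp basis for both coordinates, scaled by lambda^(-alpha/2)
    W <- rbind(cbind(Ev, matrix(0, p, sum(keep))),
               cbind(matrix(0, p, sum(keep)), Ev))
    scl <- rep(lam^(-alpha / 2), 2)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    Z <- (Xc %*% W) %*% diag(scl)
    pc <- prcomp(Z, center = FALSE, scale. = FALSE)
    sdev <- pc$sdev
    scores <- pc$x
    rotation <- W %*% diag(scl) %*% pc$rotation
  }
  nonzero <- sdev > max(sdev) * tol
  k <- sum(nonzero)
  var_pct <- 100 * sdev[nonzero]^2 / sum(sdev[nonzero]^2)

  ids <- dimnames(fit$aligned)[[3]]
  if (is.null(ids)) ids <- paste0("spec", seq_len(n))
  sc <- tibble::as_tibble(scores[, nonzero, drop = FALSE],
                          .name_repair = ~ paste0("RWS", seq_len(k)))
  sc <- dplyr::mutate(sc, specimen_id = ids,
                      centroid_size = unname(fit$centroid_size),
                      .before = 1)
  if (!is.null(fit$groups)) {
    sc <- dplyr::mutate(sc, group = unname(fit$groups),
                        .after = "specimen_id")
  }
  structure(
    list(scores = sc, var_explained = var_pct, n_warps = k,
         sdev = sdev, rotation = rotation[, nonzero, drop = FALSE],
         consensus = fit$consensus, aligned = fit$aligned, alpha = alpha),
    class = "relative_warps"
  )
}

#' @export
print.relative_warps <- function(x, ...) {
  cat("Relative warps (alpha =", x$alpha, "):", x$n_warps,
      "nonzero warps from", nrow(x$scores), "specimens\n")
  cat("  variance explained by first warps (%):",
      paste(round(head(x$var_explained, 3), 1), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy relative_warps
#' @export
tidy.relative_warps <- function(x, ...) x$scores

#' @method glance relative_warps
#' @export
glance.relative_warps <- function(x, ...) {
  tibble::tibble(n_specimens = nrow(x$scores), n_warps = x$n_warps,
                 alpha = x$alpha,
                 rws1_pct = x$var_explained[1],
                 rws1to3_pct = sum(head(x$var_explained, 3)))
}

#' Thin-plate-spline deformation grid
#'
#' Fits the thin-plate-spline interpolant carrying the consensus landmarks
#' exactly onto a target configuration and evaluates it on a rectangular
#' grid, for visualising shape change (e.g. the mean shape along RWS1 of
#' each group). A pure affine difference between target and consensus has
#' zero bending energy.
#'
#' @param consensus Reference `p x 2` matrix (or single-specimen tibble).
#' @param target Target configuration, same landmark count.
#' @param n_grid Grid lines per axis (default 24).
#' @param expand Fractional bounding-box expansion (default 0.05).
#' @return An object of class `"tps_grid"`: `grid` tibble (`row`, `col`,
#'   source `x0`,`y0` and deformed `x`,`y`), `bending_energy`, `target`,
#'   `consensus`.
#' @export
tps_grid <- function(consensus, target, n_grid = 24L, expand = 0.05) {
  ref <- .as_config_matrix(consensus)
  tgt <- .as_config_matrix(target)
  stopifnot(nrow(ref) == nrow(tgt))
  p <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 == 0, 0, d2 * log(d2)) / 2
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rhs <- rbind(tgt, matrix(0, 3, 2))
  coefs <- tryCatch(solve(L, rhs), error = function(e)
    abort("singular thin-plate-spline system: degenerate landmarks"))
  W <- coefs[seq_len(p), , drop = FALSE]
  A <- coefs[p + 1:3, , drop = FALSE]
  be <- sum(diag(t(W) %*% K %*% W))

  rng_x <- range(ref[, 1])
  rng_y <- range(ref[, 2])
  pad_x <- expand * diff(rng_x)
  pad_y <- expand * diff(rng_y)
  gx <- seq(rng_x[1] - pad_x, rng_x[2] + pad_x, length.out = n_grid)
  gy <- seq(rng_y[1] - pad_y, rng_y[2] + pad_y, length.out = n_grid)
  pts <- as.matrix(expand.grid(x = gx, y = gy))

  warp <- function(pts) {
    d2p <- outer(rowSums(pts^2), rowSums(ref^2), "+") -
      2 * pts %*% t(ref)
    d2p[d2p < 0] <- 0
    Up <- ifelse(d2p == 0, 0, d2p * log(d2p)) / 2
    cbind(1, pts) %*% A + Up %*% W
  }
  def <- warp(pts)
  grid <- tibble::tibble(
    row = rep(seq_len(n_grid), each = n_grid),
    col = rep(seq_len(n_grid), times = n_grid),
    x0 = pts[, 1], y0 = pts[, 2], x = def[, 1], y = def[, 2]
  )
  structure(
    list(grid = grid, bending_energy = be, target = tgt, consensus = ref,
         warp = warp),
    class = "tps_grid"
  )
}

#' @export
print.tps_grid <- function(x, ...) {
  cat("Thin-plate-spline grid:", nrow(x$consensus), "landmarks,",
      "bending energy", format(x$bending_energy, digits = 4), "\n")
  invisible(x)
}

#' Compare stylet shape and size across worm types
#'
#' One-way ANOVA with worm type (*M. lignano*, F1 hybrid, *M. janickei*)
#' as the fixed factor and centroid size and RWS1 as responses, each
#' followed by Tukey HSD with compact letter groupings. The hybrid stylet
#' is expected intermediate on RWS1 when shapes blend additively.
#'
#' @param rw A `"relative_warps"` object whose scores carry a `group`
#'   column.
#' @return A named list of two `"group_comparison"` objects
#'   (`centroid_size`, `RWS1`).
#' @export
compare_shape_groups <- function(rw) {
  stopifnot(inherits(rw, "relative_warps"))
  sc <- rw$scores
  if (!"group" %in% names(sc)) {
    abort("scores carry no group labels; supply groups to the landmarks")
  }
  list(
    centroid_size = compare_groups(sc, "centroid_size",
                                   family = "parametric", group = "group",
                                   log_transform = FALSE),
    RWS1 = compare_groups(sc, "RWS1", family = "parametric",
                          group = "group", log_transform = FALSE)
  )
}
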