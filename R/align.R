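kabsch <- function(ref, mov, w) {
  sw <- sum(w)
  cr <- colSums(ref * w) / sw
  cm <- colSums(mov * w) / sw
  A <- sweep(mov, 2, cm)
  B <- sweep(ref, 2, cr)
  H <- t(A * w) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- A %*% t(R)
  list(rotation = R, translation = cr, aligned = sweep(aligned, 2, cr, "+"),
       ref_centered = B, dev = sqrt(rowSums((aligned - B)^2)))
}

#' Superpose two coordinate sets by iterative weighted SVD
#'
#' Aligns `mov` onto `ref` with the Kabsch construction (weighted
#' centroid centring, optimal rotation from the SVD of the weighted
#' covariance with proper-rotation correction), then iterates: particle
#' weights are recomputed as `exp(-d_i^2 / sigma^2)` (floored at 0.1 so
#' no particle drops out of the fit entirely) with `sigma` the current
#' weighted RMSD, and the superposition repeated until the weighted RMSD
#' changes by less than `tol` or `max_iter` iterations.
#' The weights affect only the superposition; the reported `rmsd` is the
#' final unweighted all-particle value. Because annealed structures have
#' arbitrary hand, the alignment is also computed for the mirror image of
#' `mov` and the lower-RMSD result returned with a `mirrored` flag.
#'
#' @param ref,mov N x 3 coordinate matrices (N >= 3, not collinear).
#' @param weights Optional initial weights in (0, 1].
#' @param iterate If `FALSE`, perform a single (unweighted or
#'   `weights`-weighted) superposition: the classic least-squares RMSD
#'   fit.
#' @param allow_mirror Consider the reflected model (default `TRUE`).
#' @param max_iter,tol Iteration controls.
#' @return An `alignment_result`: list with `rotation` (3 x 3, proper),
#'   `translation`, `aligned` (transformed `mov`), `weights`, `rmsd`
#'   (unweighted), `per_particle_dev`, `mirrored`, `n_iter`.
#' @export
align_pair <- function(ref, mov, weights = NULL, iterate = TRUE,
                       allow_mirror = TRUE, max_iter = 10, tol = 1e-6) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov) || ncol(ref) != 3 || ncol(mov) != 3) {
    rlang::abort("ref and mov must be N x 3 matrices with equal N")
  }
  if (nrow(ref) < 3) rlang::abort("need at least 3 particles to align")
  sv <- svd(sweep(ref, 2, colMeans(ref)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    rlang::abort("degenerate (collinear) reference geometry")
  }
  run <- function(movM) {
    w <- weights %||% rep(1, nrow(ref))
    prev <- Inf
    fit <- NULL
    n_iter <- 0L
    repeat {
      fit <- kabsch(ref, movM, w)
      n_iter <- n_iter + 1L
      rmsd_w <- sqrt(sum(w * fit$dev^2) / sum(w))
      if (!iterate || n_iter >= max_iter || abs(prev - rmsd_w) < tol ||
          rmsd_w < tol) break
      prev <- rmsd_w
      # floor keeps every particle contributing to the superposition, so
      # the weighted fit cannot run away from the all-particle optimum
      w <- pmax(exp(-(fit$dev / max(rmsd_w, 1e-12))^2), 0.1)
    }
    list(fit = fit, w = w, n_iter = n_iter,
         rmsd = sqrt(mean(fit$dev^2)))
  }
  best <- run(mov)
  mirrored <- FALSE
  if (allow_mirror) {
    movm <- mov %*% diag(c(-1, 1, 1))
    alt <- run(movm)
    if (alt$rmsd < best$rmsd) {
      best <- alt
      mirrored <- TRUE
    }
  }
  structure(list(rotation = best$fit$rotation,
                 translation = best$fit$translation,
                 aligned = best$fit$aligned,
                 weights = best$w,
                 rmsd = best$rmsd,
                 per_particle_dev = best$fit$dev,
                 mirrored = mirrored,
                 n_iter = best$n_iter),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> rmsd = ", format(x$rmsd, digits = 6),
      if (x$mirrored) " (mirrored)", ", ", x$n_iter, " iteration(s)\n", sep = "")
  invisible(x)
}

#' Pairwise model precision of a genome structure
#'
#' The precision of a computed structure is the spread among its repeat
#' models: the all-particle (unweighted) RMSD after iterative weighted
#' superposition, for every model pair, summarised as the min-max range
#' over distinct pairs.
#'
#' @param structure A `genome_structure` with at least two models.
#' @param allow_mirror Allow reflection when superposing (annealing hand
#'   is arbitrary).
#' @return A `precision_summary`: list with `rmsd` (M x M symmetric
#'   matrix, zero diagonal), `range` (min, max over distinct pairs) and
#'   `mirrored` (logical matrix).
#' @export
pairwise_precision <- function(structure, allow_mirror = TRUE) {
  m <- length(structure$coords)
  if (m < 2) rlang::abort("need at least 2 models for pairwise precision")
  rmsd <- matrix(0, m, m)
  mir <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      al <- align_pair(structure$coords[[i]], structure$coords[[j]],
                       allow_mirror = allow_mirror)
      rmsd[i, j] <- rmsd[j, i] <- al$rmsd
      mir[i, j] <- mir[j, i] <- al$mirrored
    }
  }
  vals <- rmsd[upper.tri(rmsd)]
  structure(list(rmsd = rmsd, range = c(min = min(vals), max = max(vals)),
                 mirrored = mir),
            class = "precision_summary")
}

#' @export
print.precision_summary <- function(x, ...) {
  cat("<precision_summary> ", nrow(x$rmsd), " models, RMSD range ",
      sprintf("%.3f-%.3f", x$range[1], x$range[2]), " particle radii\n",
      sep = "")
  invisible(x)
}

#' Tidy pairwise precision into a long tibble
#'
#' @param x A `precision_summary`.
#' @param ... Unused.
#' @return Tibble `model1`, `model2`, `rmsd`, `mirrored` over distinct
#'   pairs.
#' @export
tidy.precision_summary <- function(x, ...) {
  m <- nrow(x$rmsd)
  idx <- which(upper.tri(x$rmsd), arr.ind = TRUE)
  tibble::tibble(model1 = idx[, 1], model2 = idx[, 2],
                 rmsd = x$rmsd[idx], mirrored = x$mirrored[idx])
}

#' One-row summary of pairwise precision
#'
#' @param x A `precision_summary`.
#' @param ... Unused.
#' @return Tibble `n_models`, `rmsd_min`, `rmsd_max`, `rmsd_mean`.
#' @export
glance.precision_summary <- function(x, ...) {
  vals <- x$rmsd[upper.tri(x$rmsd)]
  tibble::tibble(n_models = nrow(x$rmsd), rmsd_min = min(vals),
                 rmsd_max = max(vals), rmsd_mean = mean(vals))
}

#' Align models to a ground-truth conformation
#'
#' Validation support for synthetic experiments: each model is aligned
#' (mirror allowed) to known truth coordinates on an identical particle
#' table, returning per-particle deviations and per-model summaries.
#'
#' @param structure A `genome_structure`.
#' @param truth Either an N x 3 matrix matching the structure's particle
#'   table, or a list with `particles` and `coords` (as returned by
#'   [make_conformation()]).
#' @return List with `deviations` (tibble `model`, `chrom`, `start`,
#'   `deviation`) and `summary` (tibble `model`, `rmsd`, `median_dev`,
#'   `mean_dev`, `mirrored`).
#' @export
align_to_truth <- function(structure, truth) {
  if (is.list(truth) && !is.null(truth$particles)) {
    tp <- truth$particles
    if (nrow(tp) != nrow(structure$particles) ||
        !all(tp$chrom == structure$particles$chrom) ||
        !all(tp$start == structure$particles$start)) {
      rlang::abort("particle tables of structure and truth do not match")
    }
    tc <- truth$coords
  } else {
    tc <- as.matrix(truth)
    if (nrow(tc) != nrow(structure$particles)) {
      rlang::abort("particle tables of structure and truth do not match")
    }
  }
  res <- purrr::imap(structure$coords, function(co, m) {
    al <- align_pair(tc, co, allow_mirror = TRUE)
    list(dev = tibble::tibble(model = m, chrom = structure$particles$chrom,
                              start = structure$particles$start,
                              deviation = al$per_particle_dev),
         sm = tibble::tibble(model = m, rmsd = al$rmsd,
                             median_dev = stats::median(al$per_particle_dev),
                             mean_dev = mean(al$per_particle_dev),
                             mirrored = al$mirrored))
  })
  list(deviations = dplyr::bind_rows(purrr::map(res, "dev")),
       summary = dplyr::bind_rows(purrr::map(res, "sm")))
}
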