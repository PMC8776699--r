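# block-mean downsampling by an integer factor along every axis; the new
# voxel centers sit at the mean position of the pooled block, so world
# geometry is preserved
pyramid_downsample <- function(vol, f) {
  if (f == 1L) return(vol)
  d <- dim(vol$voxels)
  m <- d %/% f
  a <- vol$voxels[seq_len(m[1] * f), seq_len(m[2] * f), seq_len(m[3] * f),
                  drop = FALSE]
  dim(a) <- c(f, m[1] * m[2] * f * m[3] * f)
  a <- colMeans(a); dim(a) <- c(m[1], m[2] * f, m[3] * f)
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(f, m[2] * m[1] * m[3] * f)
  a <- colMeans(a); dim(a) <- c(m[2], m[1], m[3] * f)
  a <- aperm(a, c(3, 2, 1))
  dim(a) <- c(f, m[3] * m[1] * m[2])
  a <- colMeans(a); dim(a) <- c(m[3], m[1], m[2])
  a <- aperm(a, c(2, 3, 1))
  image_volume(a, vol$spacing * f, vol$origin + (f - 1) / 2 * vol$spacing)
}

downsample_mask <- function(mask_arr, spacing, origin, f) {
  if (f == 1L) return(mask_arr)
  v <- pyramid_downsample(image_volume(mask_arr + 0, spacing, origin), f)
  v$voxels > 0.25
}

# separable 1-2-1 blur (sigma ~ 0.7 voxel) with replicated edges. Applied to
# the secondary inside the finest-level *search* objective only: joint
# histograms of a sharp image reward grid-aligned transforms (integer-shift
# sampling avoids interpolation and keeps the histogram artificially tight),
# which can out-score the true sub-voxel alignment. Blurring the moving
# image removes that bonus; reported metrics always use the plain images.
blur_volume <- function(vol) {
  v <- vol$voxels
  for (ax in 1:3) {
    d <- dim(v)
    n <- d[ax]
    lo <- c(1, seq_len(n - 1))
    hi <- c(seq(2, n), n)
    v <- 0.5 * v + 0.25 * (switch(ax,
                                  v[lo, , , drop = FALSE],
                                  v[, lo, , drop = FALSE],
                                  v[, , lo, drop = FALSE]) +
                             switch(ax,
                                    v[hi, , , drop = FALSE],
                                    v[, hi, , drop = FALSE],
                                    v[, , hi, drop = FALSE]))
  }
  image_volume(v, vol$spacing, vol$origin)
}

default_reg_opts <- function(opts = list()) {
  utils::modifyList(list(bins = 64, clip_range = c(-200, 1500),
                         pyramid = c(4L, 2L, 1L), maxit = 800,
                         restarts = 3L, n_candidates = 8L,
                         reltol = 1e-7, grid_range = 20, grid_step = 5,
                         min_overlap = 0.25, baseline_stride = 2L,
                         hu_threshold = 650, dilation_mm = 2,
                         closing_mm = 1),
                    opts)
}

# NMI objective factory for one pyramid level. `sel` indexes the sampled
# primary voxels; returns f(par6) with an evaluation counter in its
# environment. Transforms retaining fewer than min_overlap of the samples
# score -1, which repels the (rank-based) simplex search without aborting.
make_nmi_objective <- function(prim, sec, sel, center, opts) {
  pts <- voxel_world_coords(prim)[sel, , drop = FALSE]
  a_bin <- intensity_bins(prim$voxels[sel], opts$bins,
                          opts$clip_range[1], opts$clip_range[2])
  dim_sec <- dim(sec$voxels)
  n_pts <- length(sel)
  lo <- opts$clip_range[1]; hi <- opts$clip_range[2]
  count <- 0L
  fn <- function(par) {
    count <<- count + 1L
    t <- rigid_transform(par[1], par[2], par[3], par[4], par[5], par[6],
                         center = center)
    m <- transform_matrix_form(t)
    # fold world->index conversion into the affine: idx = pts M' + v
    M <- m$R / sec$spacing # divides rows: row i of R scaled by 1/spacing[i]
    v <- (m$d - sec$origin) / sec$spacing
    idx <- pts %*% t(M)
    idx[, 1] <- idx[, 1] + v[1]
    idx[, 2] <- idx[, 2] + v[2]
    idx[, 3] <- idx[, 3] + v[3]
    counts <- cpp_joint_hist(a_bin, cpp_sample_trilinear(sec$voxels, dim_sec,
                                                         idx, NA_real_),
                             opts$bins, lo, hi)
    n <- sum(counts)
    if (n < opts$min_overlap * n_pts) return(-1)
    nmi(new_joint_histogram(counts))
  }
  list(fn = fn, n_evals = function() count)
}

# Nelder-Mead with fresh-simplex restarts: a collapsed simplex far from the
# optimum is re-seeded at its own best point until no restart improves the
# metric (or the restart budget is exhausted)
run_simplex <- function(obj, par0, step, opts, n_restarts = opts$restarts) {
  best <- NULL
  for (r in seq_len(n_restarts + 1L)) {
    res <- stats::optim(par0, obj$fn, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = opts$maxit,
                                       reltol = opts$reltol,
                                       parscale = rep(step * 10, 6)))
    if (!is.null(best) && res$value <= best$value + 1e-10) break
    best <- res
    par0 <- res$par
  }
  list(par = best$par, value = best$value,
       converged = best$convergence == 0L)
}

# Cyclic per-parameter line search: sweeps each of the 6 axes over a small
# bracket and keeps improvements. Rescues Nelder-Mead from the shallow,
# noise-rippled valleys the masked NMI shows along rotation axes, where the
# simplex collapses early; deterministic and cheap on masked samples.
axis_polish <- function(obj, par, value, span = 1.2, step = 0.15,
                        sweeps = 3L) {
  deltas <- seq(-span, span, by = step)
  deltas <- deltas[deltas != 0]
  for (s in seq_len(sweeps)) {
    improved <- FALSE
    for (j in 1:6) {
      vals <- vapply(deltas, function(d) {
        p <- par; p[j] <- p[j] + d
        obj$fn(p)
      }, numeric(1))
      if (max(vals) > value + 1e-9) {
        par[j] <- par[j] + deltas[which.max(vals)]
        value <- max(vals)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(par = par, value = value)
}

new_registration_result <- function(transform, metric_value,
                                    baseline_transform, n_evaluations,
                                    converged, pyramid_trace) {
  structure(list(transform = transform, metric_value = metric_value,
                 baseline_transform = baseline_transform,
                 n_evaluations = n_evaluations, converged = converged,
                 pyramid_trace = pyramid_trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("Rigid registration: NMI = %.4f after %d metric evaluations (%s)\n",
              x$metric_value, x$n_evaluations,
              if (x$converged) "converged" else "evaluation budget reached"))
  print(x$transform)
  invisible(x)
}

# re-express a transform about a different rotation center (same action)
reexpress <- function(t, center) {
  m <- transform_matrix_form(t)
  transform_from_matrix(m$R, m$d, center)
}

#' Whole-image baseline NMI registration
#'
#' Emulates a default rigid assist alignment: NMI over the whole image,
#' maximized by a coarse translation grid search (±20 mm, 5 mm steps) at the
#' coarsest pyramid level followed by Nelder-Mead refinement through a
#' 3-level mean-pooling pyramid (factors 4, 2, 1). Fully deterministic.
#'
#' @param primary,secondary `image_volume`s (primary = planning CT).
#' @param opts Named list overriding registration options: `bins`,
#'   `clip_range`, `pyramid`, `maxit` (per level), `reltol`, `grid_range`,
#'   `grid_step` (mm), `min_overlap`, `baseline_stride` (voxel stride used to
#'   subsample the whole image at the two finest levels).
#' @param center Rotation center; default is the primary volume center.
#' @param arbitration_mask Optional `contour_mask`. A stack of similar
#'   vertebrae makes the whole-image metric nearly periodic along the
#'   craniocaudal axis, and near-tied capture basins (alignments shifted by
#'   one level) can be hard to rank on soft-tissue-diluted whole-image NMI.
#'   When a landmark contour is available — as in the full A-RIR workflow —
#'   the candidate basins are arbitrated on the contour, where a one-level
#'   shift mismatches bone size and trabecular texture and is punished
#'   decisively.
#' @return A `registration_result`.
#' @export
register_baseline <- function(primary, secondary, opts = list(),
                              center = NULL, arbitration_mask = NULL) {
  opts <- default_reg_opts(opts)
  d <- dim(primary$voxels)
  if (is.null(center))
    center <- primary$origin + (d - 1) / 2 * primary$spacing

  # overlap precondition at identity
  jh0 <- tryCatch(joint_histogram(primary, secondary, rigid_transform(),
                                  NULL, 8, opts$clip_range),
                  error = function(e) NULL)
  if (is.null(jh0) || jh0$n < 0.10 * length(primary$voxels))
    stop("registration failure: volumes overlap by < 10% at identity",
         call. = FALSE)

  sec_smooth <- blur_volume(secondary)
  level_objective <- function(f) {
    p <- pyramid_downsample(primary, f)
    s <- pyramid_downsample(if (f == 1L) sec_smooth else secondary, f)
    sel <- seq_along(p$voxels)
    if (f <= 2L && opts$baseline_stride > 1L) {
      # whole-image histograms are statistics: in-plane subsampling at the
      # two finest levels keeps ample samples at a fraction of the cost
      dd <- dim(p$voxels)
      st <- opts$baseline_stride
      sel <- which(array(slice.index(p$voxels, 1) %% st == 0L &
                           slice.index(p$voxels, 2) %% st == 0L, dd))
    }
    make_nmi_objective(p, s, sel, center, opts)
  }

  n_evals <- 0L

  # Coarse translation grid search, keeping several candidate basins: on
  # repetitive anatomy (a stack of similar vertebrae) the coarse metric can
  # prefer an alignment shifted by one level, because mismatched slabs fall
  # outside the overlap and drop out of the histogram. Each candidate is
  # refined at the coarsest level and the survivors are arbitrated by a
  # single full-resolution evaluation, where fine image structure breaks the
  # tie, before the pyramid descent commits to one basin.
  f0 <- opts$pyramid[1]
  f_mid <- opts$pyramid[min(2L, length(opts$pyramid))]
  obj_coarse <- level_objective(f0)
  obj_fine <- level_objective(opts$pyramid[length(opts$pyramid)])
  g <- seq(-opts$grid_range, opts$grid_range, by = opts$grid_step)
  cand <- as.matrix(expand.grid(tx = g, ty = g, tz = g))
  vals <- apply(cand, 1, function(tr) obj_coarse$fn(c(tr, 0, 0, 0)))
  # spatially diverse top candidates: skip grid points adjacent to an
  # already accepted (better) one, so distinct basins all get a seat
  keep <- integer(0)
  for (i in order(vals, decreasing = TRUE)) {
    if (length(keep) >= opts$n_candidates) break
    if (length(keep) == 0L ||
        min(sqrt(rowSums(sweep(cand[keep, , drop = FALSE], 2,
                               cand[i, ])^2))) > 1.45 * opts$grid_step)
      keep <- c(keep, i)
  }
  cand_opts <- utils::modifyList(opts, list(maxit = 500))
  refined <- lapply(keep, function(i) {
    run_simplex(obj_coarse, c(cand[i, ], 0, 0, 0), step = 0.4 * f0,
                opts = cand_opts, n_restarts = 1L)
  })
  rvals <- vapply(refined, `[[`, numeric(1), "value")
  # near-tied basins are arbitrated at full resolution: each contender is
  # refined one level deeper, then briefly at the finest level, before its
  # value is compared — a coarse-level lead is not trusted to rank basins,
  # and an unrefined candidate under-reports its basin's quality. With a
  # landmark contour available, the finest arbitration runs on the contour,
  # which punishes one-level shifts far harder than the whole image does.
  contend <- order(rvals, decreasing = TRUE)[seq_len(min(3L, length(rvals)))]
  contend <- contend[rvals[contend] > max(rvals) - 0.08]
  if (length(contend) > 1L) {
    mid_opts <- utils::modifyList(opts, list(maxit = 400))
    fine_opts <- utils::modifyList(opts, list(maxit = 300))
    obj_mid <- level_objective(f_mid)
    obj_arb <- if (!is.null(arbitration_mask)) {
      make_nmi_objective(primary, sec_smooth, which(arbitration_mask$mask),
                         center, opts)
    } else {
      obj_fine
    }
    arbit <- lapply(contend, function(i) {
      pp <- run_simplex(obj_mid, refined[[i]]$par, step = 0.4 * f_mid,
                        opts = mid_opts, n_restarts = 2L)$par
      run_simplex(obj_arb, pp, step = 0.4, opts = fine_opts,
                  n_restarts = 1L)
    })
    fine_vals <- vapply(arbit, `[[`, numeric(1), "value")
    par <- arbit[[which.max(fine_vals)]]$par
    n_evals <- n_evals + obj_mid$n_evals() + obj_arb$n_evals()
  } else {
    par <- refined[[which.max(rvals)]]$par
  }
  n_evals <- n_evals + obj_coarse$n_evals()

  trace <- numeric(0)
  converged <- FALSE
  for (f in opts$pyramid) {
    obj <- if (f == f0) obj_coarse
    else if (f == opts$pyramid[length(opts$pyramid)]) obj_fine
    else level_objective(f)
    before <- obj$n_evals()
    # restarts only pay off on the coarse levels, where the init can be far;
    # the finest whole-image level is the expensive one and starts close
    r <- run_simplex(obj, par, step = 0.4 * f, opts = opts,
                     n_restarts = if (f == 1L) 0L else opts$restarts)
    if (f == opts$pyramid[length(opts$pyramid)]) {
      pol <- axis_polish(obj, r$par, r$value)
      if (pol$value > r$value) {
        r2 <- run_simplex(obj, pol$par, step = 0.2, opts = opts,
                          n_restarts = 0L)
        r <- if (r2$value >= pol$value) r2
        else list(par = pol$par, value = pol$value, converged = r$converged)
      }
    }
    if (r$value >= obj$fn(par)) par <- r$par
    trace <- c(trace, r$value)
    n_evals <- n_evals + obj$n_evals() - before
    converged <- r$converged
  }
  t_final <- rigid_transform(par[1], par[2], par[3], par[4], par[5], par[6],
                             center = center)
  new_registration_result(t_final,
                          masked_nmi(primary, secondary, t_final, NULL,
                                     opts$bins, opts$clip_range),
                          NULL, n_evals, converged, trace)
}

#' Contour-focused rigid registration (A-RIR refinement)
#'
#' Maximizes NMI restricted to the landmark contour, starting from an initial
#' transform (normally the whole-image baseline). The optimizer runs
#' Nelder-Mead through the image pyramid on the masked voxels only; the
#' returned transform is never worse than the initial one under the
#' full-resolution masked NMI.
#'
#' @param primary,secondary `image_volume`s.
#' @param mask A `contour_mask` on the primary grid (non-empty).
#' @param init Initial `rigid_transform`; defaults to identity.
#' @param opts See [register_baseline()].
#' @param center Rotation center; default is the contour centroid.
#' @return A `registration_result` with `baseline_transform = init`.
#' @export
register_contour_focused <- function(primary, secondary, mask, init = NULL,
                                     opts = list(), center = NULL) {
  opts <- default_reg_opts(opts)
  stopifnot(inherits(mask, "contour_mask"))
  if (mask$voxel_count < 1L)
    stop("empty landmark mask", call. = FALSE)
  if (is.null(center)) center <- mask_centroid(mask)
  if (is.null(init)) init <- rigid_transform(center = center)
  init <- reexpress(init, center)
  par <- coef(init)
  trace <- numeric(0)
  n_evals <- 0L
  converged <- FALSE
  sec_smooth <- blur_volume(secondary)
  fine_sel <- NULL
  for (f in opts$pyramid) {
    p <- pyramid_downsample(primary, f)
    s <- pyramid_downsample(if (f == 1L) sec_smooth else secondary, f)
    msk <- downsample_mask(mask$mask, mask$spacing, mask$origin, f)
    sel <- which(msk)
    if (length(sel) == 0L) next
    if (f == opts$pyramid[length(opts$pyramid)]) fine_sel <- sel
    obj <- make_nmi_objective(p, s, sel, center, opts)
    r <- run_simplex(obj, par, step = 0.4 * f, opts = opts)
    if (f == opts$pyramid[length(opts$pyramid)]) {
      # escape shallow rotation valleys, then let the simplex re-converge
      pol <- axis_polish(obj, r$par, r$value)
      if (pol$value > r$value) {
        r2 <- run_simplex(obj, pol$par, step = 0.2, opts = opts,
                          n_restarts = 0L)
        if (r2$value >= pol$value) {
          r <- r2
        } else {
          r <- list(par = pol$par, value = pol$value,
                    converged = r$converged)
        }
      }
    }
    if (r$value >= obj$fn(par)) par <- r$par
    trace <- c(trace, r$value)
    n_evals <- n_evals + obj$n_evals()
    converged <- r$converged
  }
  # never return a transform worse than the start, judged on the plain
  # (unsmoothed) finest-level masked metric that is also reported
  f_last <- opts$pyramid[length(opts$pyramid)]
  plain <- make_nmi_objective(pyramid_downsample(primary, f_last),
                              pyramid_downsample(secondary, f_last),
                              fine_sel, center, opts)
  v_init <- plain$fn(coef(init))
  v_final <- plain$fn(par)
  if (v_final < v_init) {
    par <- coef(init)
    v_final <- v_init
  }
  n_evals <- n_evals + 2L
  t_final <- rigid_transform(par[1], par[2], par[3], par[4], par[5], par[6],
                             center = center)
  new_registration_result(t_final, v_final, init, n_evals, converged, trace)
}

#' Fully automated contour-focused registration workflow (A-RIR)
#'
#' End-to-end pipeline: select the landmark vertebral levels from the lesion
#' annotation, extract the bone + hardware contour from the planning CT, run
#' the whole-image baseline alignment, then refine by maximizing NMI
#' restricted to the contour. Deterministic given its inputs.
#'
#' @param primary Planning CT (`image_volume`).
#' @param secondary CT-myelogram (`image_volume`).
#' @param annotation Lesion annotation: a list with `lesion_levels` (1-based)
#'   and `level_boundaries` (n_levels x 2 matrix, mm), or the path of an
#'   annotation JSON (see [read_annotation()]).
#' @param opts Registration/contour options (see [register_baseline()];
#'   contour options `hu_threshold`, `dilation_mm`, `closing_mm`).
#' @return An object of class `arir_fit`: the final `transform`, the
#'   `baseline` and `refine` registration results, the contour `mask`, and
#'   the masked NMI at baseline and at the final transform.
#' @export
run_arir_workflow <- function(primary, secondary, annotation, opts = list()) {
  opts <- default_reg_opts(opts)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  levels <- stage("contour", select_landmark_levels(
    annotation$lesion_levels, nrow(annotation$level_boundaries)))
  mask <- stage("contour", extract_landmark_mask(
    primary, levels, annotation$level_boundaries,
    hu_threshold = opts$hu_threshold, dilation_mm = opts$dilation_mm,
    closing_mm = opts$closing_mm))
  baseline <- stage("baseline", register_baseline(primary, secondary, opts,
                                                  arbitration_mask = mask))
  refine <- stage("contour-focused", register_contour_focused(
    primary, secondary, mask, init = baseline$transform, opts = opts))
  nmi_base <- masked_nmi(primary, secondary, baseline$transform, mask,
                         opts$bins, opts$clip_range)
  nmi_arir <- masked_nmi(primary, secondary, refine$transform, mask,
                         opts$bins, opts$clip_range)
  structure(list(transform = refine$transform, baseline = baseline,
                 refine = refine, mask = mask,
                 nmi_baseline = nmi_base, nmi_arir = nmi_arir,
                 levels = levels, opts = opts),
            class = "arir_fit")
}

#' @export
print.arir_fit <- function(x, ...) {
  cat("Automated contour-focused rigid registration (A-RIR)\n")
  cat(sprintf("Landmark levels: %s (%d contour voxels)\n",
              paste(x$levels, collapse = ", "), x$mask$voxel_count))
  cat(sprintf("Masked NMI: baseline %.4f -> A-RIR %.4f (improvement %+.4f)\n",
              x$nmi_baseline, x$nmi_arir, x$nmi_arir - x$nmi_baseline))
  print(x$transform)
  invisible(x)
}

#' @export
coef.arir_fit <- function(object, ...) coef(object$transform)

#' @export
summary.arir_fit <- function(object, ...) {
  out <- list(coef = coef(object),
              center = object$transform$center,
              nmi_baseline = object$nmi_baseline,
              nmi_arir = object$nmi_arir,
              delta_nmi = object$nmi_arir - object$nmi_baseline,
              n_evaluations = object$baseline$n_evaluations +
                object$refine$n_evaluations,
              voxel_count = object$mask$voxel_count,
              levels = object$levels)
  class(out) <- "summary.arir_fit"
  out
}

#' @export
print.summary.arir_fit <- function(x, ...) {
  cat("A-RIR fit summary\n")
  cat("  parameters (mm / deg):\n")
  print(round(x$coef, 4))
  cat(sprintf("  rotation center: (%.2f, %.2f, %.2f) mm\n",
              x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  masked NMI baseline/final: %.4f / %.4f (delta %+.4f)\n",
              x$nmi_baseline, x$nmi_arir, x$delta_nmi))
  cat(sprintf("  landmark levels: %s; contour voxels: %d; metric evaluations: %d\n",
              paste(x$levels, collapse = ", "), x$voxel_count,
              x$n_evaluations))
  invisible(x)
}
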