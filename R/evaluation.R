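#' Quantitative evaluation of one registered case
#'
#' Computes the masked NMI and Pearson correlation at the baseline, A-RIR and
#' H-RIR transforms (all over the same contour, the one the A-RIR extracted),
#' the NMI improvements from baseline, and the decomposition of the A-RIR
#' vs H-RIR difference into per-axis translations and per-plane rotations.
#'
#' @param primary,secondary `image_volume`s.
#' @param mask The `contour_mask` used by the A-RIR.
#' @param t_baseline,t_arir,t_hrir `rigid_transform`s in the same frame.
#' @param case_id Identifier carried into the output.
#' @param bins,clip_range Histogram options (see [joint_histogram()]).
#' @return A list of class `case_evaluation`; metric fields are `NA` (with a
#'   warning) for transforms with degenerate overlap.
#' @export
evaluate_case <- function(primary, secondary, mask, t_baseline, t_arir,
                          t_hrir, case_id = "case", bins = 64,
                          clip_range = c(-200, 1500)) {
  metric_pair <- function(t) {
    tryCatch(list(nmi = masked_nmi(primary, secondary, t, mask, bins,
                                   clip_range),
                  cc = pearson_cc(primary, secondary, t, mask)),
             error = function(e) {
               warning("metric failed for ", case_id, ": ",
                       conditionMessage(e), call. = FALSE)
               list(nmi = NA_real_, cc = NA_real_)
             })
  }
  mb <- metric_pair(t_baseline)
  ma <- metric_pair(t_arir)
  mh <- metric_pair(t_hrir)
  err <- decompose_difference(t_arir, t_hrir, center = mask_centroid(mask))
  structure(list(case_id = case_id,
                 nmi_baseline = mb$nmi, nmi_arir = ma$nmi, nmi_hrir = mh$nmi,
                 delta_nmi_arir = ma$nmi - mb$nmi,
                 delta_nmi_hrir = mh$nmi - mb$nmi,
                 cc_baseline = mb$cc, cc_arir = ma$cc, cc_hrir = mh$cc,
                 error = err),
            class = "case_evaluation")
}

#' @export
print.case_evaluation <- function(x, ...) {
  cat(sprintf("Case %s: NMI baseline/A-RIR/H-RIR = %.4f / %.4f / %.4f\n",
              x$case_id, x$nmi_baseline, x$nmi_arir, x$nmi_hrir))
  cat(sprintf("  NMI improvement: A-RIR %+.4f, H-RIR %+.4f\n",
              x$delta_nmi_arir, x$delta_nmi_hrir))
  cat(sprintf("  Pearson CC baseline/A-RIR/H-RIR = %.4f / %.4f / %.4f\n",
              x$cc_baseline, x$cc_arir, x$cc_hrir))
  print(x$error)
  invisible(x)
}

# flatten a case_evaluation into one data.frame row
case_to_row <- function(ce) {
  data.frame(case_id = ce$case_id,
             nmi_baseline = ce$nmi_baseline, nmi_arir = ce$nmi_arir,
             nmi_hrir = ce$nmi_hrir,
             delta_nmi_arir = ce$delta_nmi_arir,
             delta_nmi_hrir = ce$delta_nmi_hrir,
             cc_baseline = ce$cc_baseline, cc_arir = ce$cc_arir,
             cc_hrir = ce$cc_hrir,
             dt_ap = ce$error$dt_ap, dt_lr = ce$error$dt_lr,
             dt_cc = ce$error$dt_cc, dt_abs = ce$error$dt_abs,
             dr_axial = ce$error$dr_axial, dr_coronal = ce$error$dr_coronal,
             dr_sagittal = ce$error$dr_sagittal,
             stringsAsFactors = FALSE)
}

#' NMI loss under canonical perturbations of a registration
#'
#' Starting from a (near-)optimal transform, perturbs it by the given signed
#' translations along each patient axis and rotations in each plane, and
#' records the NMI loss `NMI(t) - NMI(perturbed t)` for each. The default
#' magnitudes (±1 mm, ±1 degree) give the 12 canonical perturbations used to
#' anchor the study's non-inferiority margin on the NMI scale.
#'
#' @param primary,secondary `image_volume`s.
#' @param t The reference `rigid_transform` (a registration optimum).
#' @param mask Optional `contour_mask`.
#' @param translations_mm Signed translation magnitudes to test per axis.
#' @param rotations_deg Signed rotation magnitudes to test per plane.
#' @param bins,clip_range Histogram options.
#' @return A data.frame with columns `kind` ("translation"/"rotation"),
#'   `axis` (lr/ap/cc or axial/coronal/sagittal), `magnitude`, `nmi`,
#'   `loss`. Zero-magnitude rows have loss exactly 0.
#' @export
perturbation_sensitivity <- function(primary, secondary, t, mask = NULL,
                                     translations_mm = c(-1, 1),
                                     rotations_deg = c(-1, 1),
                                     bins = 64, clip_range = c(-200, 1500)) {
  nmi0 <- masked_nmi(primary, secondary, t, mask, bins, clip_range)
  rows <- list()
  push <- function(kind, axis, mag, delta_args) {
    if (mag == 0) {
      nmi_p <- nmi0
    } else {
      delta <- do.call(rigid_transform, c(delta_args, list(center = t$center)))
      nmi_p <- masked_nmi(primary, secondary, compose(delta, t), mask, bins,
                          clip_range)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, axis = axis, magnitude = mag, nmi = nmi_p,
      loss = nmi0 - nmi_p, stringsAsFactors = FALSE)
  }
  tr_axes <- list(lr = "tx", ap = "ty", cc = "tz")
  rot_axes <- list(axial = "rz", coronal = "ry", sagittal = "rx")
  for (ax in names(tr_axes)) for (mag in translations_mm) {
    push("translation", ax, mag, stats::setNames(list(mag), tr_axes[[ax]]))
  }
  for (ax in names(rot_axes)) for (mag in rotations_deg) {
    push("rotation", ax, mag, stats::setNames(list(mag), rot_axes[[ax]]))
  }
  do.call(rbind, rows)
}
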