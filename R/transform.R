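#' Rigid transforms in patient coordinates
#'
#' A rigid transform is parameterized by three translations (mm) along the
#' left-right (LR, x), anterior-posterior (AP, y) and craniocaudal (CC, z)
#' axes of the LPS patient frame, and three rotations (degrees) in the
#' sagittal (about LR), coronal (about AP) and axial (about CC) planes,
#' applied intrinsically in the order axial (z), then coronal (y), then
#' sagittal (x). The action on a point p is `R (p - center) + center + t`.
#'
#' @param tx,ty,tz Translations in mm along LR (x), AP (y), CC (z).
#' @param rx,ry,rz Rotations in degrees in the sagittal, coronal and axial
#'   planes respectively.
#' @param center Rotation center, a length-3 numeric in mm (LPS).
#' @return An object of class `rigid_transform`.
#' @examples
#' t <- rigid_transform(tz = 5)
#' transform_points(t, c(0, 0, 0))
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0,
                            center = c(0, 0, 0)) {
  p <- c(tx, ty, tz, rx, ry, rz, center)
  if (length(center) != 3L || !is.numeric(p) || any(!is.finite(p)))
    stop("rigid_transform parameters must be finite numerics (center of length 3)",
         call. = FALSE)
  structure(list(tx = as.numeric(tx), ty = as.numeric(ty), tz = as.numeric(tz),
                 rx = as.numeric(rx), ry = as.numeric(ry), rz = as.numeric(rz),
                 center = as.numeric(center), frame = "LPS",
                 euler_order = "zyx"),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (LPS frame, intrinsic z-y-x Euler order)\n")
  cat(sprintf("  translation (LR, AP, CC): %.4f, %.4f, %.4f mm\n",
              x$tx, x$ty, x$tz))
  cat(sprintf("  rotation (sagittal, coronal, axial): %.4f, %.4f, %.4f deg\n",
              x$rx, x$ry, x$rz))
  cat(sprintf("  center: (%.2f, %.2f, %.2f) mm\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' @export
coef.rigid_transform <- function(object, ...) {
  c(tx = object$tx, ty = object$ty, tz = object$tz,
    rx = object$rx, ry = object$ry, rz = object$rz)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Rotation matrix of a rigid transform
#'
#' Builds the 3x3 rotation matrix `Rz(rz) %*% Ry(ry) %*% Rx(rx)` (intrinsic
#' z-y-x order, angles in degrees).
#' @param t A `rigid_transform`.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(t) {
  a <- t$rx * pi / 180; b <- t$ry * pi / 180; g <- t$rz * pi / 180
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  matrix(c(cb * cg,  cg * sb * sa - sg * ca,  cg * sb * ca + sg * sa,
           sg * cb,  sg * sb * sa + cg * ca,  sg * sb * ca - cg * sa,
           -sb,      cb * sa,                 cb * ca),
         nrow = 3, byrow = TRUE)
}

# Euler angles (degrees) from a rotation matrix under the z-y-x convention.
euler_from_matrix <- function(R) {
  sy <- -R[3, 1]
  sy <- min(1, max(-1, sy))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-12) {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
  } else {
    # gimbal lock: fold everything into rz
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
  }
  c(rx = rx, ry = ry, rz = rz) * 180 / pi
}

# (R, d) matrix form: action p -> R p + d
transform_matrix_form <- function(t) {
  R <- rotation_matrix(t)
  d <- t$center + c(t$tx, t$ty, t$tz) - as.vector(R %*% t$center)
  list(R = R, d = d)
}

# rebuild a rigid_transform from matrix form about a given center
transform_from_matrix <- function(R, d, center = c(0, 0, 0)) {
  ang <- euler_from_matrix(R)
  tr <- d - center + as.vector(R %*% center)
  rigid_transform(tr[1], tr[2], tr[3], ang["rx"], ang["ry"], ang["rz"],
                  center = center)
}

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param pts A numeric length-3 vector or an n x 3 matrix of points (mm, LPS).
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(t, pts) {
  stopifnot(is_rigid_transform(t))
  m <- transform_matrix_form(t)
  if (is.null(dim(pts))) {
    as.vector(m$R %*% pts) + m$d
  } else {
    sweep(pts %*% t(m$R), 2, m$d, "+")
  }
}

#' Compose two rigid transforms
#'
#' `compose(A, B)` acts as `A(B(p))`. The result is re-expressed about
#' `center` (default: the outer transform's center).
#'
#' @param outer,inner `rigid_transform` objects.
#' @param center Canonical center for the composed transform.
#' @return A `rigid_transform`.
#' @export
compose <- function(outer, inner, center = outer$center) {
  stopifnot(is_rigid_transform(outer), is_rigid_transform(inner))
  a <- transform_matrix_form(outer)
  b <- transform_matrix_form(inner)
  transform_from_matrix(a$R %*% b$R, as.vector(a$R %*% b$d) + a$d, center)
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @param center Canonical center for the inverse (default: `t`'s center).
#' @return A `rigid_transform` whose action is the functional inverse of `t`.
#' @export
invert <- function(t, center = t$center) {
  stopifnot(is_rigid_transform(t))
  m <- transform_matrix_form(t)
  Rt <- t(m$R)
  transform_from_matrix(Rt, -as.vector(Rt %*% m$d), center)
}

#' Decompose the difference between two registrations
#'
#' Expresses how much translation and rotation would move registration `t_b`
#' onto registration `t_a`: the parameters of `compose(invert(t_b), t_a)`,
#' reported as signed per-axis translations (mm), per-plane rotations
#' (degrees) and the absolute 3D translation.
#'
#' @param t_a,t_b `rigid_transform` objects in the same patient frame.
#' @param center Center about which the difference is expressed (default:
#'   `t_a`'s center; in the registration workflow this is the landmark
#'   contour centroid).
#' @return A list of class `transform_error` with fields `dt_lr`, `dt_ap`,
#'   `dt_cc`, `dt_abs` (mm) and `dr_axial`, `dr_coronal`, `dr_sagittal`
#'   (degrees).
#' @export
decompose_difference <- function(t_a, t_b, center = t_a$center) {
  d <- compose(invert(t_b, center = center), t_a, center = center)
  out <- list(dt_lr = d$tx, dt_ap = d$ty, dt_cc = d$tz,
              dt_abs = sqrt(d$tx^2 + d$ty^2 + d$tz^2),
              dr_axial = d$rz, dr_coronal = d$ry, dr_sagittal = d$rx)
  class(out) <- "transform_error"
  out
}

#' @export
print.transform_error <- function(x, ...) {
  cat(sprintf("Translation error (AP, LR, CC): %.3f, %.3f, %.3f mm; |t| = %.3f mm\n",
              x$dt_ap, x$dt_lr, x$dt_cc, x$dt_abs))
  cat(sprintf("Rotation error (axial, coronal, sagittal): %.3f, %.3f, %.3f deg\n",
              x$dr_axial, x$dr_coronal, x$dr_sagittal))
  invisible(x)
}

#' Read/write a rigid transform as JSON
#'
#' The serialization carries the six parameters, the rotation center, the
#' patient frame tag and the Euler order; round trips are lossless to full
#' double precision.
#'
#' @param t A `rigid_transform`.
#' @param path File path.
#' @return `read_transform` returns a `rigid_transform`; `write_transform`
#'   returns `path` invisibly.
#' @export
write_transform <- function(t, path) {
  stopifnot(is_rigid_transform(t))
  obj <- list(tx = t$tx, ty = t$ty, tz = t$tz,
              rx = t$rx, ry = t$ry, rz = t$rz,
              center = t$center, frame = t$frame, euler_order = t$euler_order)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$frame, "LPS") || !identical(obj$euler_order, "zyx"))
    stop("unsupported transform frame/euler_order: ",
         obj$frame, "/", obj$euler_order, call. = FALSE)
  rigid_transform(obj$tx, obj$ty, obj$tz, obj$rx, obj$ry, obj$rz,
                  center = obj$center)
}
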