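#' Load a 4-D diffusion volume with FSL-style gradient tables
#'
#' Reads a 4-D NIfTI diffusion volume, bval/bvec text files and a binary
#' mask, returning the masked per-voxel measurement vectors and the
#' detected acquisition protocol. Non-unit gradient columns are
#' normalised with a warning.
#'
#' @param nifti_path path to the 4-D diffusion NIfTI.
#' @param bvals_path,bvecs_path FSL-style gradient table files.
#' @param mask_path path to a 3-D binary mask NIfTI.
#' @return `list(signal, protocol, mask, voxels, dim)`: `signal` is an
#'   n_voxel x n_measurement matrix (voxels in mask order), `voxels` the
#'   corresponding 3-column voxel indices.
#' @export
load_dwi <- function(nifti_path, bvals_path, bvecs_path, mask_path) {
  img <- RNifti::readNifti(nifti_path)
  protocol <- read_bvals_bvecs(bvals_path, bvecs_path)
  mask <- RNifti::readNifti(mask_path)
  dm <- dim(img)
  if (length(dm) != 4) stop("diffusion image must be 4-D")
  if (dm[4] != length(protocol$bvals))
    stop("volume count (", dm[4], ") does not match the gradient table (",
         length(protocol$bvals), ")")
  if (!all(dim(mask) == dm[1:3])) stop("mask dimensions do not match")
  vox <- which(mask != 0, arr.ind = TRUE)
  sig <- matrix(0, nrow(vox), dm[4])
  flat <- matrix(img, prod(dm[1:3]), dm[4])
  lin <- (vox[, 3] - 1) * dm[1] * dm[2] + (vox[, 2] - 1) * dm[1] + vox[, 1]
  sig <- flat[lin, , drop = FALSE]
  list(signal = sig, protocol = protocol, mask = mask, voxels = vox,
       dim = dm[1:3])
}

#' Write per-voxel values into a NIfTI volume
#'
#' @param values numeric vector (one per voxel) or matrix (voxels x
#'   coordinates; written as a 4-D volume).
#' @param voxels 3-column matrix of voxel indices.
#' @param dim 3-vector image dimensions.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param template optional NIfTI image whose header geometry to copy.
#' @return The path, invisibly.
#' @export
write_voxel_map <- function(values, voxels, dim, path, template = NULL) {
  values <- as.matrix(values)
  k <- ncol(values)
  arr <- array(NA_real_, c(dim, k))
  lin <- (voxels[, 3] - 1) * dim[1] * dim[2] +
    (voxels[, 2] - 1) * dim[1] + voxels[, 1]
  for (j in seq_len(k)) arr[lin + (j - 1) * prod(dim)] <- values[, j]
  if (k == 1) arr <- array(arr, dim)
  img <- if (is.null(template)) RNifti::asNifti(arr)
         else RNifti::asNifti(arr, reference = template)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Group-difference statistics over summary measures
#'
#' Turns per-subject summary vectors of two groups into the inputs of the
#' change inference: the baseline `y` (group-1 mean), the observed change
#' `dy` (group-2 mean minus group-1 mean) and the noise covariance
#' `Sigma_n` (within-group covariance divided by the baseline-group size;
#' pooled across both groups when `pool = TRUE`). Both `y` and `dy` are
#' then normalised by the baseline b0 mean (see [normalize_pair()]).
#'
#' @param summaries_a,summaries_b subjects x coordinate matrices for the
#'   baseline and comparison groups (one voxel), or 3-D arrays
#'   (voxel x coordinate x subject) for voxelwise input.
#' @param pool pool the within-group covariance over both groups
#'   (default `FALSE`: baseline-group covariance divided by the
#'   baseline-group size).
#' @param normalize apply the baseline-b0 normalisation (default TRUE).
#' @param types coordinate types (`"mean"`/`"log"`) for the
#'   normalisation; defaults to the standard 5-vector layout.
#' @return For matrix input: `list(y, dy, Sigma_n, n_a, n_b)`. For array
#'   input the elements gain a leading voxel dimension.
#' @export
group_change <- function(summaries_a, summaries_b, pool = FALSE,
                         normalize = TRUE, types = NULL) {
  one <- function(A, B) {
    if (nrow(A) < 2 || nrow(B) < 2) stop("need >= 2 subjects per group")
    y <- colMeans(A)
    dy <- colMeans(B) - y
    Sn <- if (pool) {
      ((nrow(A) - 1) * stats::cov(A) + (nrow(B) - 1) * stats::cov(B)) /
        (nrow(A) + nrow(B) - 2) * (1 / nrow(A) + 1 / nrow(B))
    } else stats::cov(A) / nrow(A)
    if (normalize) {
      tp <- types
      if (is.null(tp)) tp <- c("mean", rep(c("mean", "log"),
                                           (length(y) - 1) / 2))
      attr(y, "types") <- tp
      b0 <- y[[1]]
      np <- normalize_pair(y, dy)
      sc <- ifelse(tp == "mean", 1 / b0, 1)
      Sn <- Sn * tcrossprod(sc)
      y <- np$y; dy <- np$dy
    }
    list(y = y, dy = dy, Sigma_n = Sn, n_a = nrow(A), n_b = nrow(B))
  }
  if (length(dim(summaries_a)) == 3) {
    nv <- dim(summaries_a)[1]; d <- dim(summaries_a)[2]
    Y <- matrix(NA_real_, nv, d); DY <- matrix(NA_real_, nv, d)
    SN <- array(NA_real_, c(d, d, nv))
    for (v in seq_len(nv)) {
      res <- tryCatch(one(t(summaries_a[v, , ]), t(summaries_b[v, , ])),
                      error = function(e) NULL)
      if (is.null(res)) next
      Y[v, ] <- res$y; DY[v, ] <- res$dy; SN[, , v] <- res$Sigma_n
    }
    list(y = Y, dy = DY, Sigma_n = SN,
         n_a = dim(summaries_a)[3], n_b = dim(summaries_b)[3])
  } else {
    one(as.matrix(summaries_a), as.matrix(summaries_b))
  }
}
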