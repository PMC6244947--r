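## Treatment / cell-line comparison: variable matrices from per-condition
## fits (mean parameters or predicted fold changes), the 25%-overlap
## replacement rule, per-cell-line z-scoring, and centered-SVD PCA.

#' Build the PCA variable matrix from per-condition fits
#'
#' Rows are cell line x treatment combinations; columns are RTK x parameter.
#' Two variable definitions are supported: `"param_means"` (mean log10
#' parameter values) and `"fold_change"` (predicted lysate fold change per
#' single-parameter substitution against the same cell line's control).
#' Treated cells whose parameter posterior overlaps the control posterior by
#' more than `overlap_cut` (see [overlap_fraction()]) are declared unchanged
#' and replaced by the control mean (`param_means`) or 1 (`fold_change`).
#'
#' @param fits nested list `fits[[cell_line]][[treatment]][[rtk]]`, each
#'   entry either a `rtk_fit` or a posterior sample matrix with the five
#'   kinetic columns (log10 scale); every cell line must contain a
#'   `control` treatment
#' @param mode `"param_means"` or `"fold_change"`
#' @param overlap_cut overlap fraction above which a cell is replaced
#'   (default 0.25; 0 disables replacement)
#' @param rt0 per-cell-line named vector of initial lysate totals for the
#'   fold-change simulations; defaults to 0 (fold changes from empty cells)
#' @param seed RNG seed for the overlap resampling
#' @return list of class `variable_matrix`: `matrix` (rows named
#'   "cell_line:treatment"), `cell_line` (row block labels), `overlap`
#'   (matrix of overlap fractions, NA for control rows), `mode`
#' @export
build_matrix <- function(fits, mode = c("param_means", "fold_change"),
                         overlap_cut = 0.25, rt0 = NULL, seed = NULL) {
  mode <- match.arg(mode)
  kin <- c("p_syn", "k_deg", "k_end", "k_rec", "k_shed")
  samples_of <- function(x) if (is.matrix(x)) x else posterior_samples(x)
  rows <- list(); row_names <- character(0); cell_of_row <- character(0)
  overlaps <- list()
  for (cl in names(fits)) {
    trts <- names(fits[[cl]])
    if (!"control" %in% trts) stop("cell line ", cl, " has no control fit")
    rtks <- names(fits[[cl]][["control"]])
    ctrl <- fits[[cl]][["control"]]
    ctrl_means <- lapply(ctrl, function(f) colMeans(samples_of(f)[, kin]))
    for (trt in trts) {
      have <- names(fits[[cl]][[trt]])
      if (!setequal(have, rtks)) {
        stop("condition ", cl, "/", trt, " is missing RTKs: ",
             paste(setdiff(rtks, have), collapse = ", "))
      }
      vals <- numeric(0); ovs <- numeric(0); nms <- character(0)
      for (rtk in rtks) {
        trt_samp <- samples_of(fits[[cl]][[trt]][[rtk]])[, kin, drop = FALSE]
        ctl_samp <- samples_of(ctrl[[rtk]])[, kin, drop = FALSE]
        mu_t <- colMeans(trt_samp)
        mu_c <- ctrl_means[[rtk]]
        if (mode == "fold_change") {
          r0 <- if (is.null(rt0)) 0 else rt0[[cl]]
          fc <- single_param_substitution(params_from_log10(mu_c),
                                          params_from_log10(mu_t), r0)
          cell_vals <- setNames(fc$fold_change[match(kin, fc$parameter)], kin)
        } else {
          cell_vals <- mu_t
        }
        for (p in kin) {
          ov <- if (trt == "control") NA_real_ else
            overlap_fraction(ctl_samp[, p], trt_samp[, p],
                             seed = if (is.null(seed)) NULL else
                               derive_seed(seed, paste(cl, trt, rtk, p)))
          if (!is.na(ov) && overlap_cut > 0 && ov > overlap_cut) {
            cell_vals[p] <- if (mode == "fold_change") 1 else mu_c[[p]]
          }
          ovs <- c(ovs, ov)
        }
        vals <- c(vals, cell_vals)
        nms <- c(nms, paste(rtk, kin, sep = "."))
      }
      rows[[length(rows) + 1L]] <- setNames(vals, nms)
      overlaps[[length(overlaps) + 1L]] <- setNames(ovs, nms)
      row_names <- c(row_names, paste(cl, trt, sep = ":"))
      cell_of_row <- c(cell_of_row, cl)
    }
  }
  cols <- names(rows[[1]])
  M <- do.call(rbind, lapply(rows, function(r) r[cols]))
  OV <- do.call(rbind, lapply(overlaps, function(r) r[cols]))
  rownames(M) <- rownames(OV) <- row_names
  structure(list(matrix = M, cell_line = cell_of_row, overlap = OV,
                 mode = mode),
            class = "variable_matrix")
}

#' Z-score a variable matrix within each cell line
#'
#' Standardizes every column within each cell line's row block (sample sd,
#' n - 1 denominator) so treatments are compared on a common scale per cell
#' line before the blocks are analyzed together; this absorbs absolute
#' parameter-magnitude differences between cell lines. Zero-variance
#' columns map to 0 so the matrix stays PCA-ready.
#'
#' @param vm a `variable_matrix` from [build_matrix()], or a plain matrix
#'   (then `cell_line` must be given)
#' @param cell_line row block labels when `vm` is a plain matrix
#' @return same shape as the input with standardized blocks
#' @export
zscore_by_cellline <- function(vm, cell_line = NULL) {
  is_vm <- inherits(vm, "variable_matrix")
  M <- if (is_vm) vm$matrix else as.matrix(vm)
  cl <- if (is_vm) vm$cell_line else cell_line
  if (is.null(cl) || length(cl) != nrow(M)) {
    stop("need one cell-line label per row")
  }
  for (g in unique(cl)) {
    rows <- which(cl == g)
    if (length(rows) < 2) stop("cell line ", g, " has fewer than 2 treatments")
    blk <- M[rows, , drop = FALSE]
    mu <- colMeans(blk)
    s <- apply(blk, 2, sd)
    blk <- sweep(blk, 2, mu)
    nz <- s > 0
    blk[, nz] <- sweep(blk[, nz, drop = FALSE], 2, s[nz], `/`)
    blk[, !nz] <- 0
    M[rows, ] <- blk
  }
  if (is_vm) { vm$matrix <- M; vm } else M
}

#' Principal component analysis of a variable matrix
#'
#' Column-centered SVD. Scores are the projections of the rows, loadings the
#' right singular vectors; explained-variance fractions are the normalized
#' squared singular values. Component signs are fixed by making the
#' largest-magnitude loading of each component positive.
#'
#' @param vm a `variable_matrix` or plain matrix (rows = conditions)
#' @param n_components number of components to keep (default all)
#' @return list with `scores`, `loadings`, `explained_variance`, `center`
#' @export
run_pca <- function(vm, n_components = NULL) {
  M <- if (inherits(vm, "variable_matrix")) vm$matrix else as.matrix(vm)
  if (nrow(M) < 2) stop("PCA needs at least 2 rows")
  center <- colMeans(M)
  X <- sweep(M, 2, center)
  if (all(X == 0)) stop("degenerate matrix: all rows identical")
  sv <- svd(X)
  k <- min(n_components %||% length(sv$d), length(sv$d))
  d <- sv$d[seq_len(k)]
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  ## deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(d, k)
  dimnames(scores) <- list(rownames(M), paste0("PC", seq_len(k)))
  dimnames(V) <- list(colnames(M), paste0("PC", seq_len(k)))
  list(scores = scores, loadings = V,
       explained_variance = sv$d^2 / sum(sv$d^2),
       center = center)
}
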