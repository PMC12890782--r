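CELLS <- c("congruent_correct", "congruent_error",
           "incongruent_correct", "incongruent_error")
ALIGNMENTS <- c("flanker", "response")

#' Condition-averaged ERPs for one participant-visit
#'
#' Averages z-scored epochs within each of the four condition cells
#' (congruent/incongruent x correct/error) for each alignment. Cells with
#' fewer than `min_trials` trials are flagged unusable and excluded from any
#' downstream averaging.
#'
#' @param epochs_by_alignment named list with elements `flanker` and
#'   `response`, each a z-scored [epoch_set()].
#' @param min_trials minimum trials per cell.
#' @return object of class `resdyn_erps`: `erp[[alignment]][[cell]]` is a
#'   channels x time matrix (or NULL), plus `counts` and `usable` matrices
#'   (cell x alignment).
#' @export
condition_erps <- function(epochs_by_alignment, min_trials = 6) {
  counts <- matrix(0L, length(CELLS), length(ALIGNMENTS),
                   dimnames = list(CELLS, ALIGNMENTS))
  erp <- setNames(vector("list", length(ALIGNMENTS)), ALIGNMENTS)
  for (al in ALIGNMENTS) {
    es <- epochs_by_alignment[[al]]
    stopifnot(inherits(es, "resdyn_epochs"))
    erp[[al]] <- setNames(vector("list", length(CELLS)), CELLS)
    for (cl in CELLS) {
      idx <- which(es$info$cell == cl)
      counts[cl, al] <- length(idx)
      if (length(idx) >= 1) {
        m <- es$data[idx, , , drop = FALSE]
        erp[[al]][[cl]] <- apply(m, c(2, 3), mean)
      }
    }
  }
  usable <- counts >= min_trials
  if (!any(usable))
    stop("participant excluded: no condition cell reaches min_trials = ", min_trials)
  structure(list(erp = erp, counts = counts, usable = usable,
                 min_trials = min_trials,
                 channel_names = epochs_by_alignment[[1]]$channel_names,
                 times = epochs_by_alignment[[1]]$times),
            class = "resdyn_erps")
}

#' Time-concatenated grand-average ERP matrix
#'
#' Averages each cell's ERP across all participant-visits with equal weight
#' (skipping flagged cells), then concatenates the 8 blocks
#' (alignment-major, then condition, then time) into an
#' N channels x M (= 2 alignments x 4 conditions x T) matrix. The fixed
#' column order makes the concatenation reproducible bit-for-bit.
#'
#' @param erp_list list of [condition_erps()] results.
#' @return N x M matrix with attribute `"block_index"` describing columns.
#' @export
build_grand_matrix <- function(erp_list) {
  stopifnot(length(erp_list) >= 1)
  ch <- erp_list[[1]]$channel_names
  for (e in erp_list)
    if (!identical(e$channel_names, ch)) stop("inconsistent channel sets")
  Tn <- length(erp_list[[1]]$times)
  blocks <- list(); block_ix <- list()
  for (al in ALIGNMENTS) for (cl in CELLS) {
    acc <- matrix(0, length(ch), Tn); n_used <- 0L
    for (e in erp_list) {
      if (isTRUE(e$usable[cl, al])) { acc <- acc + e$erp[[al]][[cl]]; n_used <- n_used + 1L }
    }
    if (n_used == 0L) next
    blocks[[paste(al, cl, sep = ".")]] <- acc / n_used
    block_ix[[paste(al, cl, sep = ".")]] <-
      data.frame(alignment = al, cell = cl, time = erp_list[[1]]$times)
  }
  if (!length(blocks)) stop("no usable condition cells across participants")
  G <- do.call(cbind, blocks)
  attr(G, "block_index") <- do.call(rbind, block_ix)
  rownames(G) <- ch
  G
}

#' Principal-component state space from the grand ERP
#'
#' Centers each channel's row of the grand matrix over columns, forms the
#' N x N channel covariance and eigendecomposes it. The first two
#' eigenvectors span the shared 2D state space; explained-variance fractions
#' are reported for all components. Each weight column's sign is fixed so its
#' largest-magnitude channel weight is positive.
#'
#' @param grand N x M matrix from [build_grand_matrix()] (M > 2).
#' @return object of class `resdyn_space`: `weights` (N x 2, orthonormal),
#'   `explained_var` (length N, sums to 1), `center` (per-channel row means),
#'   `channel_names`, `grand_dims`.
#' @export
pca_space <- function(grand) {
  stopifnot(is.matrix(grand), ncol(grand) > 2)
  ctr <- rowMeans(grand)
  Gc <- grand - ctr
  C <- tcrossprod(Gc) / (ncol(grand) - 1)
  ev <- eigen(C, symmetric = TRUE)
  if (sum(ev$values > max(ev$values) * 1e-12) < 2)
    stop("grand ERP covariance has rank < 2")
  W <- ev$vectors[, 1:2, drop = FALSE]
  for (k in 1:2) if (W[which.max(abs(W[, k])), k] < 0) W[, k] <- -W[, k]
  structure(list(weights = W,
                 explained_var = ev$values / sum(ev$values),
                 center = ctr,
                 channel_names = rownames(grand),
                 grand_dims = dim(grand)),
            class = "resdyn_space")
}

#' @export
print.resdyn_space <- function(x, ...) {
  cat("State space:", length(x$channel_names), "channels -> 2 PCs;",
      sprintf("PC1+PC2 explain %.1f%% of variance\n",
              100 * sum(x$explained_var[1:2])))
  invisible(x)
}

#' Project single-trial epochs into the shared state space
#'
#' Rigid linear map `t(weights) %*% epoch` applied to every trial of an
#' alignment; the space is never re-fit per participant.
#'
#' @param epochs a z-scored [epoch_set()].
#' @param space a [pca_space()].
#' @return latent trial set: list(data = trials x 2 x time array, times,
#'   alignment, info).
#' @export
project_trials <- function(epochs, space) {
  if (!identical(epochs$channel_names, space$channel_names))
    stop("channel mismatch between epochs and state space: epochs have [",
         paste(head(epochs$channel_names), collapse = ", "), " ...]")
  n <- dim(epochs$data)[1]; Tn <- dim(epochs$data)[3]
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), dim(epochs$data)[2], n * Tn)
  lat <- crossprod(space$weights, flat)              # 2 x (n*Tn)
  out <- array(0, c(n, 2, Tn))
  for (d in 1:2) out[, d, ] <- matrix(lat[d, ], n, Tn)
  list(data = out, times = epochs$times, alignment = epochs$alignment,
       info = epochs$info)
}

#' Trial-by-trial residuals in the state space
#'
#' Subtracts the condition-cell mean latent trajectory from each trial:
#' \eqn{x_{ijt} = s_{ijt} - \bar s_{jt}}. Trials belonging to cells below
#' `min_trials` are excluded (counted in attribute `"n_excluded"`). Within
#' every retained cell the residuals average to zero at each component and
#' time point by construction.
#'
#' @param latents output of [project_trials()].
#' @param min_trials minimum trials for a usable cell.
#' @return residual set: list(data = trials x 2 x time, times, alignment,
#'   info, cell_means); attribute `"n_excluded"`.
#' @export
residuals_latent <- function(latents, min_trials = 6) {
  cell <- latents$info$cell
  keep <- rep(FALSE, length(cell))
  cm <- list()
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < min_trials) next
    keep[idx] <- TRUE
    cm[[cl]] <- apply(latents$data[idx, , , drop = FALSE], c(2, 3), mean)
  }
  if (!any(keep)) stop("no usable cells for residuals")
  res <- latents$data[keep, , , drop = FALSE]
  kcell <- cell[keep]
  Tn <- dim(res)[3]
  for (cl in names(cm)) {
    idx <- which(kcell == cl)
    for (d in 1:2)
      res[idx, d, ] <- matrix(res[idx, d, ], length(idx), Tn) -
        matrix(cm[[cl]][d, ], length(idx), Tn, byrow = TRUE)
  }
  out <- list(data = res, times = latents$times, alignment = latents$alignment,
              info = latents$info[keep, , drop = FALSE], cell_means = cm)
  attr(out, "n_excluded") <- sum(!keep)
  out
}
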