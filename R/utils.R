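# Internal helpers shared across modules.

#' Derive a reproducible stage seed from a master seed
#'
#' Each stochastic stage draws from its own substream so results do not depend
#' on the order in which stages execute. The stage label is hashed onto a
#' 31-bit offset that is combined with the master seed.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(master) + h * 1009) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one compartment of an ICF table as a sample-by-cell-type matrix
#'
#' @param icf an ICF table: data.frame with `sample_id`, `compartment`, and one
#'   numeric column per cell type, rows summing to 1.
#' @param compartment `"blood"` or `"tumor"`.
#' @return Numeric matrix, rownames are sample ids.
#' @export
icf_matrix <- function(icf, compartment) {
  stopifnot(is.data.frame(icf), compartment %in% c("blood", "tumor"))
  sub <- icf[icf$compartment == compartment, , drop = FALSE]
  types <- setdiff(colnames(icf), c("sample_id", "compartment"))
  m <- as.matrix(sub[, types, drop = FALSE])
  rownames(m) <- sub$sample_id
  m
}

assert_icf_rows <- function(m, tol = 1e-9) {
  if (any(m < -tol)) stop("ICF values must be nonnegative")
  if (any(abs(rowSums(m) - 1) > tol)) stop("ICF rows must sum to 1")
  invisible(TRUE)
}

# Deterministic row normalization to the simplex after clipping at zero.
clip_renormalize <- function(m) {
  m[m < 0] <- 0
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("cannot renormalize an all-zero fraction row")
  sweep(m, 1, rs, "/")
}

pb_key <- function(sample_id, compartment, cell_type) {
  paste(sample_id, compartment, cell_type, sep = "|")
}
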