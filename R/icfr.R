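#' Enumerate canonical immune-cell-fraction ratio (ICFR) forms
#'
#' ICFRs have the form `(ICF[c1] +/- ICF[c2]) / (ICF[c3] + ICF[c4])` where the
#' four slots range over cell types with repetition, so the family subsumes
#' simple ratios such as `c1/c2` (via repeated slots). The canonicalization
#' emitted here: plus numerators are unordered pairs with repetition
#' (`c1 <= c2`); minus numerators are sign-deduplicated ordered pairs
#' (`c1 < c2`, so each difference appears once); denominators are unordered
#' pairs with repetition (`c3 <= c4`); constant forms are excluded (a plus
#' numerator may not equal its denominator as a multiset, and minus
#' numerators exclude `c1 == c2`).
#'
#' @param cell_types at least two cell type names.
#' @return data.frame of forms: `c1`, `c2`, `sign` (`"plus"`/`"minus"`),
#'   `c3`, `c4`, `label`, in a deterministic order.
#' @examples
#' nrow(enumerate_icfr_forms(c("A", "B"))) # 9
#' @export
enumerate_icfr_forms <- function(cell_types) {
  cts <- sort(unique(cell_types))
  if (length(cts) < 2) stop("need at least 2 cell types")
  k <- length(cts)
  pairs_rep <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, seq(i, k))))  # unordered with repetition
  pairs_lt <- pairs_rep[pairs_rep[, 1] < pairs_rep[, 2], , drop = FALSE]
  denom <- data.frame(c3 = cts[pairs_rep[, 1]], c4 = cts[pairs_rep[, 2]],
                      stringsAsFactors = FALSE)
  num_minus <- data.frame(c1 = cts[pairs_lt[, 1]], c2 = cts[pairs_lt[, 2]],
                          sign = "minus", stringsAsFactors = FALSE)
  num_plus <- data.frame(c1 = cts[pairs_rep[, 1]], c2 = cts[pairs_rep[, 2]],
                         sign = "plus", stringsAsFactors = FALSE)
  nums <- rbind(num_minus, num_plus)
  grid <- merge(nums, denom, by = NULL) # cross join
  # exclude constant-1 forms: plus numerator equal to denominator multiset
  const1 <- grid$sign == "plus" & grid$c1 == grid$c3 & grid$c2 == grid$c4
  grid <- grid[!const1, , drop = FALSE]
  op <- ifelse(grid$sign == "plus", "+", "-")
  grid$label <- paste0("(", grid$c1, op, grid$c2, ")/(",
                       grid$c3, "+", grid$c4, ")")
  grid <- grid[order(grid$sign, grid$c1, grid$c2, grid$c3, grid$c4), ,
               drop = FALSE]
  rownames(grid) <- NULL
  grid[, c("c1", "c2", "sign", "c3", "c4", "label")]
}

#' The memory-B/Treg ratio signature form
#'
#' The preset `(B_memory - Treg)/(B_memory + Treg)`, bounded in `[-1, 1]` for
#' nonnegative fractions and antisymmetric under swapping the two types.
#'
#' @param b_memory,treg the cell type names used in the ICF table.
#' @return A one-row ICFR form data.frame.
#' @export
icfr_star_form <- function(b_memory = "B_memory", treg = "Treg") {
  data.frame(c1 = b_memory, c2 = treg, sign = "minus",
             c3 = b_memory, c4 = treg,
             label = paste0("(", b_memory, "-", treg, ")/(",
                            b_memory, "+", treg, ")"),
             stringsAsFactors = FALSE)
}

#' Evaluate an ICFR form on one ICF row
#'
#' @param icf_row named numeric vector of cell-type fractions.
#' @param form one-row ICFR form (as in [enumerate_icfr_forms()]).
#' @return `(icf[c1] +/- icf[c2]) / (icf[c3] + icf[c4])`, or `NA` when the
#'   denominator is zero.
#' @export
icfr_value <- function(icf_row, form) {
  cts <- unlist(form[1, c("c1", "c2", "c3", "c4")])
  missing_ct <- setdiff(cts, names(icf_row))
  if (length(missing_ct))
    stop("unknown cell type(s): ", paste(missing_ct, collapse = ", "))
  num <- if (form$sign[1] == "plus") {
    icf_row[[form$c1[1]]] + icf_row[[form$c2[1]]]
  } else {
    icf_row[[form$c1[1]]] - icf_row[[form$c2[1]]]
  }
  den <- icf_row[[form$c3[1]]] + icf_row[[form$c4[1]]]
  if (den == 0) return(NA_real_)
  num / den
}

#' Evaluate an ICFR form on every row of an ICF matrix
#'
#' @param icf_mat sample-by-cell-type matrix (see [icf_matrix()]).
#' @param form one-row ICFR form.
#' @return Named numeric vector per sample; `NA` where the denominator is 0.
#' @export
icfr_values <- function(icf_mat, form) {
  cts <- unlist(form[1, c("c1", "c2", "c3", "c4")])
  missing_ct <- setdiff(cts, colnames(icf_mat))
  if (length(missing_ct))
    stop("unknown cell type(s): ", paste(missing_ct, collapse = ", "))
  num <- if (form$sign[1] == "plus") {
    icf_mat[, form$c1[1]] + icf_mat[, form$c2[1]]
  } else {
    icf_mat[, form$c1[1]] - icf_mat[, form$c2[1]]
  }
  den <- icf_mat[, form$c3[1]] + icf_mat[, form$c4[1]]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
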