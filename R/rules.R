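#' Extract fuzzy IF-THEN rules from a fitted model
#'
#' One rule per antecedent label cell of each submodel. The consequent is
#' read from the submodel's predicted contribution at the cell's apex
#' combination (which, for a tensor of triangular sets, is exactly the
#' cell's coefficient), min-max normalized over that submodel's cells to
#' `s` in `[0, 1]`: the rule concludes `High` with membership degree `s`
#' when `s >= 0.5`, otherwise `Low` with membership degree `1 - s`.
#'
#' @param model An [asmod_fit()] model.
#' @return Data frame with columns `output`, `submodel`, one antecedent
#'   column per ion used by the model (label or `NA` when the ion is not in
#'   the rule's submodel), `consequent`, and `MD`; degenerate (constant)
#'   submodels yield `MD = 0.5` rules flagged in `degenerate`.
#' @export
extract_rules <- function(model) {
  ions_used <- unlist(lapply(model$submodels, `[[`, "ions"))
  rows <- list()
  for (k in seq_along(model$submodels)) {
    s <- model$submodels[[k]]
    cells <- expand.grid(lapply(s$partitions, `[[`, "labels"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    names(cells) <- s$ions
    # tensor_basis enumerates later ions fastest; expand.grid varies the
    # first column fastest, so reorder cells to the coefficient order
    ord <- do.call(order, lapply(s$ions, function(i)
      match(cells[[i]], s$partitions[[i]]$labels)))
    cells <- cells[ord, , drop = FALSE]
    cellpred <- s$coef
    rngc <- range(cellpred)
    degenerate <- diff(rngc) < 1e-12
    sc <- if (degenerate) rep(0.5, length(cellpred)) else
      (cellpred - rngc[1]) / diff(rngc)
    for (i in seq_len(nrow(cells))) {
      ant <- stats::setNames(rep(NA_character_, length(ions_used)), ions_used)
      ant[s$ions] <- unlist(cells[i, , drop = TRUE])
      rows[[length(rows) + 1]] <- data.frame(
        output = model$output, submodel = k, t(ant),
        consequent = if (sc[i] >= 0.5) "High" else "Low",
        MD = if (sc[i] >= 0.5) sc[i] else 1 - sc[i],
        degenerate = degenerate,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(output = character(), submodel = integer(),
                      consequent = character(), MD = numeric(),
                      degenerate = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dominance ranges of a fitted model
#'
#' The fuzzify dominance intervals of every ion used by the model's
#' submodels: the concentration ranges in which each linguistic label
#' (low/mid/high) is the dominant description of the input.
#'
#' @param model An [asmod_fit()] model.
#' @return Data frame with columns `output`, `ion`, `level`, `lo`, `hi`.
#' @export
dominance_ranges <- function(model) {
  rows <- list()
  for (s in model$submodels) {
    for (ion in s$ions) {
      d <- dominance(s$partitions[[ion]])
      rows[[length(rows) + 1]] <- data.frame(output = model$output,
                                             ion = ion, d)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(output = character(), ion = character(),
                      level = character(), lo = numeric(), hi = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
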