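# State-specific elastic networks: harmonic distance restraints between
# backbone bead pairs within a cutoff, the "rubber bands" that hold a
# coarse-grained protein in one conformation.

#' Build an elastic network from bead coordinates
#'
#' Emits one harmonic term per bead pair whose distance is at or below the
#' cutoff and whose residue separation is at least `min_seq_sep`. Each
#' term's minimum `b0` is the measured distance and its force constant the
#' given `k`. Defaults follow common Martini practice: 500 kJ/mol/nm^2 and
#' a 0.9 nm cutoff. First neighbours (`min_seq_sep = 2` excludes them) are
#' covered by regular backbone bonds, not the network.
#'
#' @param s a [bead_structure()] (typically [select_backbone()] output).
#' @param cutoff distance cutoff in nm; pairs at exactly the cutoff are
#'   included.
#' @param k force constant in kJ/mol/nm^2.
#' @param min_seq_sep minimum |residue_i - residue_j|.
#' @param exclude_pairs optional two-column matrix (or data frame) of bead
#'   index pairs to omit.
#' @param source_label `"A"` or `"B"`, recorded for provenance.
#' @return Object of class `elastic_network` with a `terms` data frame
#'   (`i`, `j`, `b0`, `k`; `i < j`, sorted by `(i, j)`).
#' @export
build_network <- function(s, cutoff = 0.9, k = 500, min_seq_sep = 2,
                          exclude_pairs = NULL, source_label = "") {
  stopifnot(inherits(s, "bead_structure"))
  if (!is.numeric(cutoff) || cutoff <= 0) {
    abort_enmix("cutoff must be positive", "enmix_parameter_error")
  }
  if (k < 0) abort_enmix("force constant must be >= 0", "enmix_parameter_error")
  xyz <- coords(s)
  resid <- s$beads$residue_index
  idx <- s$beads$index
  n <- nrow(xyz)
  terms <- list()
  if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    pair <- which(upper.tri(d), arr.ind = TRUE)
    keep <- d[pair] <= cutoff &
      abs(resid[pair[, 1]] - resid[pair[, 2]]) >= min_seq_sep
    pair <- pair[keep, , drop = FALSE]
    terms <- data.frame(
      i = idx[pair[, 1]], j = idx[pair[, 2]],
      b0 = d[pair], k = rep(k, nrow(pair))
    )
    if (!is.null(exclude_pairs) && NROW(exclude_pairs) > 0) {
      ep <- as.matrix(exclude_pairs)
      key_ep <- paste(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2]))
      key <- paste(pmin(terms$i, terms$j), pmax(terms$i, terms$j))
      terms <- terms[!(key %in% key_ep), , drop = FALSE]
    }
    terms <- terms[order(terms$i, terms$j), , drop = FALSE]
    rownames(terms) <- NULL
  }
  if (length(terms) == 0 || nrow(terms) == 0) {
    terms <- data.frame(i = integer(0), j = integer(0),
                        b0 = numeric(0), k = numeric(0))
  }
  residue_of <- stats::setNames(resid, idx)
  structure(
    list(terms = terms, cutoff = cutoff, default_k = k,
         min_seq_sep = min_seq_sep, source_label = source_label,
         residue_of = residue_of),
    class = "elastic_network"
  )
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("<elastic_network%s> %d terms, cutoff %.3g nm, k %.4g kJ/mol/nm^2\n",
              if (nzchar(x$source_label)) paste0(" ", x$source_label) else "",
              nrow(x$terms), x$cutoff, x$default_k))
  invisible(x)
}

#' @export
length.elastic_network <- function(x) nrow(x$terms)

#' Remove network terms touching given residues
#'
#' Deletes every restraint with at least one bead in the listed residues —
#' the operation used to release disordered fragments, and, with
#' `residues` equal to all residues, to construct a fully unrestrained
#' (unfolded) state model.
#'
#' @param net an `elastic_network`.
#' @param residues integer vector of residue indices; empty set is the
#'   identity.
#' @return The stripped `elastic_network`.
#' @export
strip_network <- function(net, residues) {
  stopifnot(inherits(net, "elastic_network"))
  if (length(residues) == 0) return(net)
  res_i <- net$residue_of[as.character(net$terms$i)]
  res_j <- net$residue_of[as.character(net$terms$j)]
  keep <- !(res_i %in% residues | res_j %in% residues)
  net$terms <- net$terms[keep, , drop = FALSE]
  rownames(net$terms) <- NULL
  net
}

#' Format a network as GROMACS rubber-band bond lines
#'
#' Produces the comment-marked block conventionally placed inside the
#' `[bonds]` directive of a Martini topology.
#'
#' @param net an `elastic_network`.
#' @param funct GROMACS bond function type (default 6, harmonic without
#'   exclusion generation).
#' @return Character vector of lines including the `; Rubber band` marker.
#' @export
format_rubber_band <- function(net, funct = 6) {
  stopifnot(inherits(net, "elastic_network"))
  c("; Rubber band",
    sprintf("%5d %5d %3d %10.5f %10.1f",
            net$terms$i, net$terms$j, funct, net$terms$b0, net$terms$k))
}
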