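## Cold-inducibility typing of homeolog triplets.
##
## A gene is cold-induced when its DE call is "up" (log2FC > 1, p < 0.01,
## strictly). A triplet with 3 / 2 / 1 induced copies is Type 1 / 2 / 3;
## none induced is untyped. Within Type 1 triplets the copies are ranked
## by inducibility — the FPKM fold change cold vs control with a 0.1 FPKM
## pseudo-count — and a triplet whose rank-1 inducibility is at least
## twice its rank-3 inducibility is flagged divergent.

#' Extract the cold-induced gene set from DE results
#'
#' @param deResults output of [deTest()] (needs `gene` and `call`).
#' @return character vector of up-regulated gene ids; down-regulated
#'   genes are never part of the induced set.
#' @export
coldInducedSet <- function(deResults) {
  if (nrow(deResults) == 0) return(character())
  as.character(deResults$gene[deResults$call == "up"])
}

#' Rank the copies of a triplet by cold inducibility
#'
#' @param inducibility named numeric length 3, per-copy FPKM fold change
#'   cold vs control. Ties are broken lexicographically by gene id.
#' @param divergentRatio flag threshold; rank-1 / rank-3 >= this is
#'   divergent (default 2, "two-fold or greater").
#' @return list with `ranks` (named integer, 1 = most inducible) and
#'   `flag` ("divergent" or "similar").
#' @examples
#' rankInducibility(c(x = 8, y = 3, z = 2))$flag   # divergent (8/2 = 4)
#' rankInducibility(c(x = 3, y = 2.9, z = 2.8))$flag  # similar
#' @export
rankInducibility <- function(inducibility, divergentRatio = 2) {
  stopifnot(length(inducibility) == 3)
  o <- order(-inducibility, names(inducibility))
  ranks <- integer(3); ranks[o] <- 1:3
  names(ranks) <- names(inducibility)
  ratio <- inducibility[o[1]] / inducibility[o[3]]
  list(ranks = ranks,
    flag = if (ratio >= divergentRatio) "divergent" else "similar",
    ratio = unname(ratio))
}

#' Type every triplet's cold response
#'
#' @param tripletMap a [TripletMap-class].
#' @param inducedSet character vector of cold-induced gene ids (from
#'   [coldInducedSet()]).
#' @param fpkm FPKM matrix over all samples (genes x samples).
#' @param condition "control"/"cold" per sample of `fpkm`.
#' @param pseudoFPKM pseudo-count added to both means before the
#'   inducibility ratio (default 0.1 FPKM), so zero-control genes stay
#'   finite.
#' @param divergentRatio divergence flag threshold (default 2).
#' @return a [S4Vectors::DataFrame], one row per triplet: anchor, type
#'   (type1/type2/type3/none), nInduced, per-copy inducibility and rank,
#'   and the divergence flag (divergent/similar for Type 1, "n/a"
#'   otherwise).
#' @export
classifyColdTypes <- function(tripletMap, inducedSet, fpkm, condition,
                              pseudoFPKM = 0.1, divergentRatio = 2) {
  mem <- tripletMembers(tripletMap)
  condition <- as.character(condition)
  ctrlMean <- rowMeans(fpkm[, condition == "control", drop = FALSE])
  coldMean <- rowMeans(fpkm[, condition == "cold", drop = FALSE])
  ind <- (coldMean + pseudoFPKM) / (ctrlMean + pseudoFPKM)
  n <- length(anchors(tripletMap))
  out <- data.frame(
    anchor = anchors(tripletMap),
    copy1 = mem[, 1], copy2 = mem[, 2], copy3 = mem[, 3],
    nInduced = NA_integer_, type = NA_character_,
    ind1 = NA_real_, ind2 = NA_real_, ind3 = NA_real_,
    rank1 = NA_integer_, rank2 = NA_integer_, rank3 = NA_integer_,
    divergent = "n/a", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- mem[i, ]
    k <- sum(g %in% inducedSet)
    out$nInduced[i] <- k
    out$type[i] <- switch(as.character(k),
      "3" = "type1", "2" = "type2", "1" = "type3", "0" = "none")
    ri <- rankInducibility(ind[g], divergentRatio)
    out$ind1[i] <- ind[g[1]]; out$ind2[i] <- ind[g[2]]
    out$ind3[i] <- ind[g[3]]
    out$rank1[i] <- ri$ranks[1]; out$rank2[i] <- ri$ranks[2]
    out$rank3[i] <- ri$ranks[3]
    if (out$type[i] == "type1") out$divergent[i] <- ri$flag
  }
  res <- DataFrame(out, row.names = out$anchor)
  metadata(res) <- list(pseudoFPKM = pseudoFPKM,
    divergentRatio = divergentRatio,
    divergenceDefinition = "rank-1 vs rank-3 inducibility")
  res
}

#' Summarize cold-response types
#'
#' @param types output of [classifyColdTypes()].
#' @return list with per-type counts, the typed-triplet total, the percent
#'   of typed triplets that are Type 2 or 3 (diverged cold response,
#'   nearest integer), and the percent of Type 1 triplets flagged
#'   divergent (one decimal).
#' @export
summarizeColdTypes <- function(types) {
  if (nrow(types) == 0 || !any(types$type != "none")) {
    warning("no typed triplets")
    return(list(counts = c(type1 = 0L, type2 = 0L, type3 = 0L),
      nTyped = 0L, percentType23 = NA_real_,
      nType1Divergent = 0L, percentType1Divergent = NA_real_))
  }
  counts <- c(type1 = sum(types$type == "type1"),
    type2 = sum(types$type == "type2"),
    type3 = sum(types$type == "type3"))
  nTyped <- sum(counts)
  n1div <- sum(types$type == "type1" & types$divergent == "divergent")
  list(counts = counts, nTyped = nTyped,
    percentType23 = percentage(counts[["type2"]] + counts[["type3"]],
      nTyped, 0),
    nType1Divergent = n1div,
    percentType1Divergent = if (counts[["type1"]] > 0)
      percentage(n1div, counts[["type1"]], 1) else NA_real_)
}
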