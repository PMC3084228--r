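# Signed off-target -> pathway -> effect network and qualitative propagation
# of off-target inhibition.
#
# Propagation is a fixpoint over the lattice unknown < {up, down} < mixed:
# activation edges preserve the incoming direction, inhibition edges flip it,
# dual edges yield mixed. The fixpoint terminates on cyclic graphs; on DAGs
# it coincides with aggregating all simple paths from the perturbed sources.

#' Load a signed network from a TSV edge list
#'
#' Required columns: \code{source, target, sign, source_kind, target_kind}.
#' Duplicate edges collapse to one; conflicting signs collapse to
#' \code{dual} with a warning.
#'
#' @param path TSV file path.
#' @return SignedNetwork.
#' @export
loadNetwork <- function(path) {
  df <- .readTSV(path)
  need <- c("source", "target", "sign", "source_kind", "target_kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("network schema error: missing column(s) ", paste(miss, collapse = ", "))
  badSign <- setdiff(unique(df$sign), .EDGE_SIGNS)
  if (length(badSign))
    stop("network schema error: unknown sign token(s) ",
         paste(badSign, collapse = ", "))
  badKind <- setdiff(unique(c(df$source_kind, df$target_kind)), .NODE_KINDS)
  if (length(badKind))
    stop("network schema error: unknown kind token(s) ",
         paste(badKind, collapse = ", "))
  nodes <- unique(rbind(data.frame(id = df$source, kind = df$source_kind,
                                   stringsAsFactors = FALSE),
                        data.frame(id = df$target, kind = df$target_kind,
                                   stringsAsFactors = FALSE)))
  dupNode <- nodes$id[duplicated(nodes$id)]
  if (length(dupNode))
    stop("network schema error: conflicting kinds for node(s) ",
         paste(unique(dupNode), collapse = ", "))
  key <- paste(df$source, df$target)
  edges <- df[!duplicated(key), c("source", "target", "sign")]
  for (k in unique(key[duplicated(key)])) {
    signs <- unique(df$sign[key == k])
    if (length(signs) > 1L) {
      warning("conflicting duplicate edge ", k, " collapsed to 'dual'")
      edges$sign[paste(edges$source, edges$target) == k] <- "dual"
    }
  }
  rownames(edges) <- NULL
  new("SignedNetwork", nodes = nodes, edges = edges)
}

#' Build a signed network from data frames
#'
#' @param nodes data.frame with columns \code{id, kind}.
#' @param edges data.frame with columns \code{source, target, sign}.
#' @export
signedNetwork <- function(nodes, edges)
  new("SignedNetwork", nodes = nodes, edges = edges)

.DIR_UNKNOWN <- 0L; .DIR_UP <- 1L; .DIR_DOWN <- 2L; .DIR_MIXED <- 3L

.joinDir <- function(a, b) {
  # lattice join: unknown < {up, down} < mixed
  if (a == .DIR_UNKNOWN) return(b)
  if (b == .DIR_UNKNOWN) return(a)
  if (a == b) return(a)
  .DIR_MIXED
}

.edgeImage <- function(dir, sign) {
  if (dir == .DIR_UNKNOWN) return(.DIR_UNKNOWN)
  if (sign == "dual" || dir == .DIR_MIXED) return(.DIR_MIXED)
  if (sign == "activation") dir
  else if (dir == .DIR_UP) .DIR_DOWN else .DIR_UP
}

#' Propagate the effect of inhibiting off-target nodes
#'
#' Each inhibited off-target starts at direction \code{down}; along an edge,
#' activation preserves the direction, inhibition flips it and a dual edge
#' yields \code{mixed}. A node's direction is the lattice join over all
#' incoming signals (agreement keeps the pure direction, disagreement or any
#' mixed signal gives \code{mixed}); nodes unreachable from every perturbed
#' source stay \code{unchanged}. Computed as a monotone fixpoint, so cyclic
#' networks terminate.
#'
#' @param net SignedNetwork.
#' @param inhibited character ids of off_target nodes to inhibit.
#' @return PerturbationResult; \code{n_up}/\code{n_down} count incoming
#'   supporting signals (edges delivering that direction) per node.
#' @export
propagateInhibition <- function(net, inhibited) {
  nodes <- net@nodes; edges <- net@edges
  bad <- setdiff(inhibited, nodes$id)
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  kind <- nodes$kind[match(inhibited, nodes$id)]
  if (any(kind != "off_target"))
    stop("only off_target nodes can be inhibited (offending: ",
         paste(inhibited[kind != "off_target"], collapse = ", "), ")")
  n <- nrow(nodes)
  dir <- setNames(rep(.DIR_UNKNOWN, n), nodes$id)
  dir[inhibited] <- .DIR_DOWN
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      img <- .edgeImage(dir[[edges$source[e]]], edges$sign[e])
      nd <- .joinDir(dir[[edges$target[e]]], img)
      if (nd != dir[[edges$target[e]]]) { dir[edges$target[e]] <- nd; changed <- TRUE }
    }
    if (!changed) break
  }
  nUp <- setNames(integer(n), nodes$id); nDown <- nUp
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    img <- .edgeImage(dir[[edges$source[e]]], edges$sign[e])
    if (img == .DIR_UP) nUp[edges$target[e]] <- nUp[edges$target[e]] + 1L
    if (img == .DIR_DOWN) nDown[edges$target[e]] <- nDown[edges$target[e]] + 1L
  }
  nDown[inhibited] <- nDown[inhibited] + 1L  # the perturbation itself
  lab <- c("unchanged", "up", "down", "mixed")[dir + 1L]
  new("PerturbationResult",
      directions = data.frame(id = nodes$id, kind = nodes$kind,
                              direction = lab, n_up = unname(nUp),
                              n_down = unname(nDown),
                              stringsAsFactors = FALSE),
      inhibited = as.character(inhibited))
}

#' Summarize a propagation result
#'
#' @param net SignedNetwork the result was computed on.
#' @param result PerturbationResult.
#' @param path optional TSV output for the summary table.
#' @return data.frame restricted to pathway and effect nodes (stable
#'   ordering: kind, then id), printed as a plain-text report when
#'   \code{verbose}.
#' @param verbose print the report to the console.
#' @export
reportPerturbation <- function(net, result, path = NULL, verbose = FALSE) {
  d <- result@directions
  sel <- d[d$kind %in% c("pathway", "effect"), , drop = FALSE]
  sel <- sel[order(match(sel$kind, c("pathway", "effect")), sel$id), ,
             drop = FALSE]
  rownames(sel) <- NULL
  if (verbose) {
    cat(sprintf("Inhibited off-targets: %s\n",
                paste(result@inhibited, collapse = ", ")))
    for (r in seq_len(nrow(sel)))
      cat(sprintf("  %-8s %-24s %-9s (support: %d down, %d up)\n",
                  sel$kind[r], sel$id[r], sel$direction[r],
                  sel$n_down[r], sel$n_up[r]))
  }
  if (!is.null(path)) .writeTSV(sel, path)
  sel
}

#' Bundled off-target signalling network
#'
#' Loads the illustrative kinase off-target network shipped with the
#' package: predicted off-target kinases wired to the PI3K/Akt, MAPK, JNK,
#' NF-kB, mTOR, glucose-uptake and glycogenolysis pathways through
#' intermediate proteins, with downstream cellular effects. The topology is
#' a hand-curated approximation for demonstration, not a ground-truth
#' pathway database.
#'
#' @return SignedNetwork.
#' @export
offtargetNetwork <- function()
  loadNetwork(system.file("extdata", "offtarget_network.tsv",
                          package = "offtargetr"))
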