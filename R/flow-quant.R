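# Hierarchical gating of event tables, subpopulation fractions, quadrant
# splits and mean fluorescence intensity.

#' Define a gate node
#'
#' A predicate on one channel (`min <= x < max`) or a 2-D rectangle on two
#' channels. `min`/`max` may be `-Inf`/`Inf`.
#'
#' @param name node name.
#' @param parent parent node name (`NULL` for the root).
#' @param channel channel name, or two channel names for a rectangle.
#' @param min,max bounds (scalars, or length-2 for a rectangle).
#' @return a `gate_node` list.
#' @export
gate_node <- function(name, parent = NULL, channel, min = -Inf, max = Inf) {
  stopifnot(length(channel) %in% 1:2, length(min) == length(channel),
            length(max) == length(channel))
  structure(list(name = name, parent = parent, channel = channel,
                 min = min, max = max), class = "gate_node")
}

#' Assemble a gate tree
#'
#' @param ... `gate_node`s. Exactly one must have `parent = NULL` (the
#'   root, conventionally the live gate); every other node's parent must be
#'   defined before it.
#' @return object of class `gate_tree`.
#' @export
gate_tree <- function(...) {
  nodes <- list(...)
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  roots <- vapply(nodes, function(n) is.null(n$parent), logical(1))
  if (sum(roots) != 1) stop("gate tree must have exactly one root")
  for (n in nodes)
    if (!is.null(n$parent) && !n$parent %in% names(nodes))
      stop("undefined parent: ", n$parent)
  structure(list(nodes = nodes, root = names(nodes)[roots]),
            class = "gate_tree")
}

#' Apply a gate tree to an event table
#'
#' Membership is computed top-down; an event belongs to a node iff it
#' satisfies the node's predicate and its parent's membership, so every
#' event's node set is a root-to-node chain.
#'
#' @param events an `event_table` (or any data.frame of channel columns).
#' @param tree a [gate_tree()].
#' @return logical matrix, events x nodes.
#' @export
apply_gate_tree <- function(events, tree) {
  stopifnot(inherits(tree, "gate_tree"))
  m <- matrix(FALSE, nrow = nrow(events), ncol = length(tree$nodes),
              dimnames = list(NULL, names(tree$nodes)))
  for (nm in names(tree$nodes)) {
    n <- tree$nodes[[nm]]
    ok <- rep(TRUE, nrow(events))
    for (i in seq_along(n$channel)) {
      x <- events[[n$channel[i]]]
      if (is.null(x)) stop("event table lacks channel: ", n$channel[i])
      ok <- ok & x >= n$min[i] & x < n$max[i]
    }
    if (!is.null(n$parent)) ok <- ok & m[, n$parent]
    m[, nm] <- ok
  }
  m
}

#' Fraction of a gated population relative to an ancestor gate
#'
#' @param membership matrix from [apply_gate_tree()].
#' @param node,denominator_node node names; the denominator must be on the
#'   node's ancestor chain (checked by containment).
#' @return fraction in `[0, 1]` (0 when the denominator is empty).
#' @export
population_fraction <- function(membership, node, denominator_node) {
  a <- membership[, node]; b <- membership[, denominator_node]
  if (any(a & !b))
    stop("denominator is not an ancestor of node (containment violated)")
  if (sum(b) == 0) return(0)
  sum(a) / sum(b)
}

#' Quadrant fractions within a gated population
#'
#' @param events event table rows already restricted to the parent gate.
#' @param x_channel,y_channel channel names (conventionally F4/80 and the
#'   reporter).
#' @param x_threshold,y_threshold quadrant thresholds.
#' @return named numeric vector of the four fractions
#'   (`yhi_xlo`, `ylo_xlo`, `yhi_xhi`, `ylo_xhi`), summing to 1.
#' @export
quadrant_fractions <- function(events, x_channel, x_threshold,
                               y_channel, y_threshold) {
  n <- nrow(events)
  if (n == 0) stop("no events in parent gate")
  xhi <- events[[x_channel]] >= x_threshold
  yhi <- events[[y_channel]] >= y_threshold
  c(yhi_xlo = sum(yhi & !xhi), ylo_xlo = sum(!yhi & !xhi),
    yhi_xhi = sum(yhi & xhi), ylo_xhi = sum(!yhi & xhi)) / n
}

#' Mean fluorescence intensity of a population
#'
#' Arithmetic mean on the linear scale by default; geometric mean behind
#' `geometric = TRUE`.
#'
#' @param events event table rows for the population.
#' @param channel channel name.
#' @param geometric use the geometric mean.
#' @return scalar MFI; `NA` with a warning for an empty population.
#' @export
mfi <- function(events, channel, geometric = FALSE) {
  x <- events[[channel]]
  if (length(x) == 0) {
    warning("MFI undefined: empty population")
    return(NA_real_)
  }
  if (geometric) exp(mean(log(x))) else mean(x)
}

#' Default hierarchical microglial gate tree
#'
#' live -> CD11b+CD45+ -> Ly6C-Ly6G- (microglia) -> reporter+/- leaves.
#' Thresholds sit at the log-scale midpoints of the population models'
#' high/low states.
#'
#' @param reporter_channel name of the reporter channel (`"EYFP"`).
#' @return a [gate_tree()].
#' @export
default_microglia_gates <- function(reporter_channel = "EYFP") {
  thr_myeloid <- exp((log(1000) + log(15)) / 2)   # CD11b/CD45 hi vs debris
  thr_ly6 <- exp((log(20) + log(1500)) / 2)       # Ly6C/G low vs monocyte/neutrophil
  thr_rep <- exp((log(25) + log(1500)) / 2)
  gate_tree(
    gate_node("live", NULL, "viability", min = 0),
    gate_node("myeloid", "live", c("CD11b", "CD45"),
              min = c(thr_myeloid, thr_myeloid), max = c(Inf, Inf)),
    gate_node("microglia", "myeloid", c("Ly6C", "Ly6G"),
              min = c(0, 0), max = c(thr_ly6, thr_ly6)),
    gate_node("reporter_neg", "microglia", reporter_channel, max = thr_rep),
    gate_node("reporter_pos", "microglia", reporter_channel, min = thr_rep)
  )
}
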