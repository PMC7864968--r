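# Tissue-compartment networks.
#
# The traffic network is a star around a hub (serum) carrying lipids from an
# origin (liver) to termini (CNS, heart, adipose).  Edges are read
# origin -> terminus; each edge is an "axis" labelled with a pair of
# one-letter compartment codes, e.g. LS = liver -> serum.

#' Construct a compartment network
#'
#' @param nodes Character vector of compartment names.
#' @param edges Two-column matrix or data.frame of directed edges
#'   (\code{from}, \code{to}), read origin to terminus.
#' @param origin Origin compartment (the site of de novo lipogenesis).
#' @param hub Hub compartment through which all traffic passes.
#' @param termini Character vector of terminal compartments.
#' @return A \code{compartment_network}: list with \code{nodes},
#'   \code{edges} (data.frame \code{from}, \code{to}, \code{label}),
#'   \code{origin}, \code{hub}, \code{termini} and the per-node letter
#'   \code{codes} used to build axis labels.
#' @export
compartment_network <- function(nodes, edges, origin, hub, termini) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("from", "to")
  stopifnot(
    is.character(nodes), anyDuplicated(nodes) == 0L,
    all(c(edges$from, edges$to) %in% nodes),
    origin %in% nodes, hub %in% nodes, all(termini %in% nodes)
  )
  # hub must touch the origin and every terminus
  touch <- function(a, b) {
    any((edges$from == a & edges$to == b) | (edges$from == b & edges$to == a))
  }
  if (!touch(origin, hub)) {
    stop("hub '", hub, "' is not adjacent to origin '", origin, "'")
  }
  for (t in termini) {
    if (!touch(hub, t)) stop("hub '", hub, "' is not adjacent to terminus '", t, "'")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_connected(g)) stop("network is not connected")

  codes <- .assign_letter_codes(nodes)
  edges$label <- paste0(codes[edges$from], codes[edges$to])
  if (anyDuplicated(edges$label) > 0L) stop("axis labels are not unique")

  structure(
    list(nodes = nodes, edges = edges, origin = origin, hub = hub,
         termini = termini, codes = codes),
    class = "compartment_network"
  )
}

# One-letter code per compartment: the first letter of the name not already
# taken; if all letters of the name are taken, the first free letter A-Z.
# Deterministic in node order.
.assign_letter_codes <- function(nodes) {
  used <- character(0)
  codes <- character(length(nodes))
  for (i in seq_along(nodes)) {
    letters_of <- unique(strsplit(toupper(gsub("[^A-Za-z]", "", nodes[i])),
                                  "")[[1]])
    free <- setdiff(letters_of, used)
    code <- if (length(free) > 0L) free[1] else setdiff(LETTERS, used)[1]
    if (is.na(code)) stop("ran out of letter codes for '", nodes[i], "'")
    codes[i] <- code
    used <- c(used, code)
  }
  stats::setNames(codes, nodes)
}

#' Preset networks for the three study groups
#'
#' \code{"F1N"}: liver-serum-\{brain, heart\} (adipose is not dissectible in
#' neonates and the neonatal brain is profiled whole).
#' \code{"F1A"}: liver-serum-\{cerebellum, right brain, heart, adipose\}.
#' \code{"F2N"}: liver-serum-\{cerebellum, right brain, heart\}.
#'
#' @param name One of \code{"F1N"}, \code{"F1A"}, \code{"F2N"}.
#' @return A \code{compartment_network}.
#' @examples
#' preset_network("F1N")
#' @export
preset_network <- function(name) {
  presets <- list(
    F1N = list(termini = c("brain", "heart")),
    F1A = list(termini = c("cerebellum", "right brain", "heart", "adipose")),
    F2N = list(termini = c("cerebellum", "right brain", "heart"))
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available presets: ",
         paste(names(presets), collapse = ", "))
  }
  termini <- presets[[name]]$termini
  nodes <- c("liver", "serum", termini)
  edges <- data.frame(
    from = c("liver", rep("serum", length(termini))),
    to = c("serum", termini),
    stringsAsFactors = FALSE
  )
  compartment_network(nodes, edges, origin = "liver", hub = "serum",
                      termini = termini)
}

#' Enumerate the axes of a network
#'
#' @param network A \code{compartment_network}.
#' @return data.frame with one row per axis: \code{from}, \code{to},
#'   \code{label} (directional two-letter code, read origin to terminus).
#' @export
axes <- function(network) {
  stopifnot(inherits(network, "compartment_network"))
  network$edges[, c("from", "to", "label")]
}

#' Neighbours of a compartment
#' @param network A \code{compartment_network}.
#' @param compartment Compartment name.
#' @return Character vector of adjacent compartments.
#' @export
neighbours_of <- function(network, compartment) {
  stopifnot(compartment %in% network$nodes)
  e <- network$edges
  unique(c(e$to[e$from == compartment], e$from[e$to == compartment]))
}

#' @export
print.compartment_network <- function(x, ...) {
  cat("<compartment_network> ", length(x$nodes), " compartments, ",
      nrow(x$edges), " axes\n", sep = "")
  cat("  origin: ", x$origin, "  hub: ", x$hub, "\n", sep = "")
  cat("  axes: ", paste(x$edges$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convert a network to an igraph object
#' @param network A \code{compartment_network}.
#' @return An undirected \code{igraph} graph with edge attribute
#'   \code{label}.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "compartment_network"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = data.frame(name = network$nodes))
}

#' Write a network as a DOT file
#' @param network A \code{compartment_network}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_network_dot <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "dot")
  invisible(path)
}

#' Read a network from a config list
#'
#' Accepts either \code{list(preset = "F1N")} or an explicit definition
#' \code{list(nodes=, edges=, origin=, hub=, termini=)} as parsed from a
#' YAML/JSON config block.
#'
#' @param config Named list.
#' @return A \code{compartment_network}.
#' @export
network_from_config <- function(config) {
  if (!is.null(config$preset)) return(preset_network(config$preset))
  edges <- config$edges
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      data.frame(from = e[[1]], to = e[[2]], stringsAsFactors = FALSE)
    }))
  }
  compartment_network(unlist(config$nodes), edges, config$origin,
                      config$hub, unlist(config$termini))
}
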