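# Independent oracles and small constructors used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force Jaccard p-value: enumerate every pair of subsets of the
# universe with the observed sizes and count those at least as dissimilar.
brute_jaccard_pvalue <- function(x, y, universe) {
  m <- length(x); n <- length(y)
  j_obs <- length(intersect(x, y)) / length(union(x, y))
  subsets <- function(k) {
    if (k == 0L) return(list(character(0)))
    utils::combn(universe, k, simplify = FALSE)
  }
  xs <- subsets(m); ys <- subsets(n)
  tot <- 0L; hits <- 0L
  for (a in xs) for (b in ys) {
    tot <- tot + 1L
    un <- length(union(a, b))
    jp <- if (un == 0L) NA_real_ else length(intersect(a, b)) / un
    if (!is.na(jp) && jp <= j_obs + 1e-12) hits <- hits + 1L
  }
  hits / tot
}

# Brute-force A/B/U categorisation from per-compartment presence sets:
# decide each variable's fate directly from its compartment-membership
# pattern, independently of the set algebra in categorize().
brute_categorize <- function(sets, network) {
  vars <- unique(unlist(sets))
  ax <- axes(network)
  A <- character(0)
  B <- stats::setNames(rep(list(character(0)), nrow(ax)), ax$label)
  U <- stats::setNames(rep(list(character(0)), length(network$nodes)),
                       network$nodes)
  for (v in vars) {
    where <- names(sets)[vapply(sets, function(s) v %in% s, logical(1))]
    if (setequal(where, network$nodes)) {
      A <- c(A, v)
      next
    }
    for (i in seq_len(nrow(ax))) {
      if (ax$from[i] %in% where && ax$to[i] %in% where) {
        B[[ax$label[i]]] <- c(B[[ax$label[i]]], v)
      }
    }
    for (cc in where) {
      if (!any(neighbours_of(network, cc) %in% where)) {
        U[[cc]] <- c(U[[cc]], v)
      }
    }
  }
  list(A = sort(A), B = lapply(B, sort), U = lapply(U, sort))
}

# Hand-built presence map from per-phenotype, per-compartment sets:
# entries = list(phenotype = list(compartment = character vector)).
make_presence <- function(entries, compartments) {
  phenotypes <- names(entries)
  pooled <- stats::setNames(lapply(compartments, function(cc)
    sort(unique(unlist(lapply(entries, `[[`, cc))))), compartments)
  structure(
    list(phenotypes = phenotypes, compartments = compartments,
         entries = entries, pooled = pooled,
         sample_counts = matrix(1L, length(compartments),
                                length(phenotypes),
                                dimnames = list(compartments, phenotypes)),
         no_data = data.frame(compartment = character(0),
                              phenotype = character(0)),
         variables = sort(unique(unlist(entries)))),
    class = "presence_map"
  )
}

# Random per-compartment presence sets over a variable pool.
random_sets <- function(network, n_vars = 20L) {
  vars <- paste0("x", seq_len(n_vars))
  stats::setNames(lapply(network$nodes, function(cc)
    vars[stats::runif(n_vars) < 0.5]), network$nodes)
}

# A three-compartment chain used in the toy categorisation examples.
toy_chain <- function() {
  compartment_network(
    nodes = c("liver", "serum", "brain"),
    edges = data.frame(from = c("liver", "serum"),
                       to = c("serum", "brain")),
    origin = "liver", hub = "serum", termini = "brain")
}
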