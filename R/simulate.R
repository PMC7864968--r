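# Seeded generator of multi-compartment, two-phenotype lipidomics datasets
# with known ground truth: every variable's compartment membership is drawn
# per category (A/B/U), re-routings and abundance effects are planted
# explicitly, and the manifest records everything, so each analysis stage
# can be tested for exact recovery.

# Class pool with sum-composition ranges and log-normal location offsets.
# TGs dominate the positive-mode signal; phospholipids sit lower.
.lipid_class_pool <- function() {
  data.frame(
    class  = c("TG", "DG", "PC", "PE", "SM", "PC-O", "PE-O", "LPC",
               "Cer", "PI", "PS", "PG"),
    weight = c(30, 8, 20, 14, 6, 4, 3, 4, 4, 3, 2, 2),
    c_min  = c(40, 28, 30, 30, 30, 30, 30, 14, 30, 32, 32, 30),
    c_max  = c(60, 40, 44, 44, 42, 40, 40, 22, 42, 42, 42, 40),
    d_max  = c(10, 6, 8, 8, 3, 6, 6, 4, 2, 6, 6, 5),
    loc    = c(3.0, 1.5, 2.5, 2.0, 1.5, 1.0, 0.8, 1.0, 0.5, 0.6, 0.4, 0.4),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic lipid-traffic scenario
#'
#' Defaults emulate the study design: a preset traffic network, two
#' phenotype groups of 8 samples per compartment, ~300 lipid variables
#' spread over the common classes with log-normal abundances (multiplicative
#' noise, sdlog 0.3, i.e. ~30\% CV — typical for semi-quantitative
#' lipidomics), and a small per-value detection dropout.
#'
#' @param network Preset name (\code{"F1N"}, \code{"F1A"}, \code{"F2N"}) or
#'   a \code{compartment_network}.
#' @param control,experimental Phenotype labels.
#' @param n_samples Samples per (compartment, phenotype).
#' @param n_variables Total number of lipid variables.
#' @param category_probs Probabilities that a variable is A (ubiquitous),
#'   B (one axis) or U (one compartment).
#' @param noise_scale sdlog of the log-normal abundance noise.
#' @param dropout Per-value probability that a present signal is zeroed
#'   (detection dropout).
#' @param planted_reroutes List of \code{list(variable, from_axis,
#'   to_axis)}; \code{variable = "auto"} lets the generator dedicate a
#'   variable and record it in the manifest.
#' @param planted_effects List of \code{list(variable, compartment, fold)};
#'   \code{variable = "auto"} picks a ubiquitous variable.
#' @param mode Ionisation-mode label stamped on the samples.
#' @param seed Integer seed; the same config and seed give byte-identical
#'   output.
#' @return A \code{scenario_config} list.
#' @export
scenario_config <- function(network = "F1N",
                            control = "NP-NC", experimental = "LP-HC",
                            n_samples = 8L, n_variables = 300L,
                            category_probs = c(A = 0.5, B = 0.3, U = 0.2),
                            noise_scale = 0.3, dropout = 0.05,
                            planted_reroutes = list(),
                            planted_effects = list(),
                            mode = "positive", seed = 1L) {
  if (is.character(network)) network <- preset_network(network)
  stopifnot(inherits(network, "compartment_network"),
            n_samples >= 1L, n_variables >= 1L,
            length(category_probs) == 3L, all(category_probs >= 0),
            noise_scale >= 0, dropout >= 0, dropout <= 1)
  structure(
    list(network = network, control = control, experimental = experimental,
         n_samples = as.integer(n_samples),
         n_variables = as.integer(n_variables),
         category_probs = category_probs / sum(category_probs),
         noise_scale = noise_scale, dropout = dropout,
         planted_reroutes = planted_reroutes,
         planted_effects = planted_effects,
         mode = mode, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Generate a synthetic dataset with a ground-truth manifest
#'
#' Draws a variable list, assigns each variable a compartment membership
#' realising its category, plants the requested re-routings (membership =
#' from-axis endpoints in the control phenotype, to-axis endpoints in the
#' experimental one) and abundance effects (multiplicative mean shift in
#' one compartment of the experimental group), then emits a
#' signal-corrected table.
#'
#' @param config A \code{scenario_config}.
#' @return List with \code{table} (a corrected \code{lta_table}) and
#'   \code{manifest}: \code{variables} (data.frame: variable, class,
#'   category, location), \code{reroutes} and \code{effects} (resolved,
#'   with variable names), \code{loc} (per-variable log-normal location)
#'   and the \code{config}.
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  net <- config$network
  ax <- axes(net)

  pool <- .lipid_class_pool()
  vars <- character(0); cls <- character(0)
  while (length(vars) < config$n_variables) {
    need <- config$n_variables - length(vars)
    i <- sample.int(nrow(pool), need, replace = TRUE, prob = pool$weight)
    cand <- sprintf("%s(%d:%d)", pool$class[i],
                    vapply(i, function(j)
                      sample(seq(pool$c_min[j], pool$c_max[j]), 1L),
                      integer(1)),
                    vapply(i, function(j) sample(0:pool$d_max[j], 1L),
                           integer(1)))
    keep <- !duplicated(cand) & !cand %in% vars
    vars <- c(vars, cand[keep]); cls <- c(cls, pool$class[i][keep])
  }
  loc <- pool$loc[match(cls, pool$class)]

  # Membership per variable, identical in both phenotypes until planted.
  category <- sample(c("A", "B", "U"), config$n_variables, replace = TRUE,
                     prob = config$category_probs)
  location <- character(config$n_variables)
  membership <- function(cat, where) {
    switch(cat,
           A = net$nodes,
           B = {i <- match(where, ax$label); c(ax$from[i], ax$to[i])},
           U = where)
  }
  location[category == "B"] <- sample(ax$label, sum(category == "B"),
                                      replace = TRUE)
  location[category == "U"] <- sample(net$nodes, sum(category == "U"),
                                      replace = TRUE)
  location[category == "A"] <- "all"
  member_ctrl <- lapply(seq_along(vars), function(i)
    membership(category[i], location[i]))
  member_expt <- member_ctrl

  axis_ends <- function(lab) {
    i <- match(lab, ax$label)
    if (is.na(i)) stop("planted re-route on non-existent axis '", lab, "'")
    c(ax$from[i], ax$to[i])
  }
  resolve <- function(name, eligible) {
    if (identical(name, "auto")) {
      i <- eligible[1]
      if (is.na(i)) stop("no eligible variable left for an auto plant")
      i
    } else {
      i <- match(name, vars)
      if (is.na(i)) stop("planted variable '", name,
                         "' not in the generated variable list")
      i
    }
  }

  planted_idx <- integer(0)
  reroutes <- data.frame(variable = character(0), from_axis = character(0),
                         to_axis = character(0), stringsAsFactors = FALSE)
  for (rr in config$planted_reroutes) {
    from_e <- axis_ends(rr$from_axis); to_e <- axis_ends(rr$to_axis)
    if (length(intersect(from_e, to_e)) == 0L) {
      stop("planted re-route axes '", rr$from_axis, "' and '", rr$to_axis,
           "' share no endpoint")
    }
    i <- resolve(rr$variable, setdiff(seq_along(vars), planted_idx))
    planted_idx <- c(planted_idx, i)
    member_ctrl[[i]] <- from_e
    member_expt[[i]] <- to_e
    category[i] <- "rerouted"
    location[i] <- paste(rr$from_axis, rr$to_axis, sep = "->")
    reroutes <- rbind(reroutes, data.frame(
      variable = vars[i], from_axis = rr$from_axis, to_axis = rr$to_axis,
      stringsAsFactors = FALSE))
  }

  effects <- data.frame(variable = character(0), compartment = character(0),
                        fold = numeric(0), stringsAsFactors = FALSE)
  for (ef in config$planted_effects) {
    if (!ef$compartment %in% net$nodes) {
      stop("planted effect in non-existent compartment '",
           ef$compartment, "'")
    }
    eligible <- setdiff(which(category == "A"), planted_idx)
    i <- resolve(ef$variable, eligible)
    if (!(ef$compartment %in% member_ctrl[[i]] &&
          ef$compartment %in% member_expt[[i]])) {
      stop("planted effect variable '", vars[i],
           "' is not present in compartment '", ef$compartment,
           "' for both phenotypes")
    }
    planted_idx <- c(planted_idx, i)
    effects <- rbind(effects, data.frame(
      variable = vars[i], compartment = ef$compartment, fold = ef$fold,
      stringsAsFactors = FALSE))
  }

  phenos <- c(config$control, config$experimental)
  members <- list(member_ctrl, member_expt)
  sample_rows <- list(); value_rows <- list()
  for (p in seq_along(phenos)) {
    for (cc in net$nodes) {
      present <- vapply(members[[p]], function(m) cc %in% m, logical(1))
      vmat <- matrix(0, nrow = config$n_samples, ncol = length(vars))
      npres <- sum(present)
      if (npres > 0L) {
        vmat[, present] <- matrix(
          stats::rlnorm(config$n_samples * npres,
                        meanlog = rep(loc[present], each = config$n_samples),
                        sdlog = config$noise_scale),
          nrow = config$n_samples)
        if (config$dropout > 0) {
          drop <- matrix(stats::runif(config$n_samples * npres) <
                           config$dropout, nrow = config$n_samples)
          vmat[, present][drop] <- 0
        }
      }
      if (p == 2L && nrow(effects) > 0L) {
        for (k in seq_len(nrow(effects))) {
          if (effects$compartment[k] == cc) {
            j <- match(effects$variable[k], vars)
            vmat[, j] <- vmat[, j] * effects$fold[k]
          }
        }
      }
      ids <- sprintf("%s_%s_%02d", gsub(" ", "", cc), phenos[p],
                     seq_len(config$n_samples))
      sample_rows[[length(sample_rows) + 1L]] <- data.frame(
        sample_id = ids, compartment = cc, phenotype = phenos[p],
        generation = "synthetic", mode = config$mode,
        petrol_washed = FALSE, stringsAsFactors = FALSE)
      value_rows[[length(value_rows) + 1L]] <- vmat
    }
  }
  values <- do.call(rbind, value_rows)
  colnames(values) <- vars
  samples <- do.call(rbind, sample_rows)

  table <- signal_correct(lta_table(values, samples))
  manifest <- list(
    variables = data.frame(variable = vars, class = cls,
                           category = category, location = location,
                           stringsAsFactors = FALSE),
    reroutes = reroutes, effects = effects, loc = stats::setNames(loc, vars),
    config = config)
  list(table = table, manifest = manifest)
}

#' Small named fixture scenarios
#'
#' Worked examples used throughout the tests and documentation:
#' \describe{
#'   \item{jtc_two_thirds}{The three-versus-two variable lists whose
#'     Jaccard-Tanimoto coefficient is 2/3 with resampling p-value 1.}
#'   \item{null_dataset}{An F1N-shaped dataset with every variable
#'     ubiquitous and no planted effects (for false-positive-rate checks).}
#'   \item{f1n_reroute}{An F1N-shaped dataset with one variable moved from
#'     the serum-heart axis (control) to the serum-brain axis
#'     (experimental), zero dropout.}
#' }
#'
#' @return Named list; the dataset entries hold \code{table} and
#'   \code{manifest} as returned by [generate()].
#' @export
fixture_suite <- function() {
  list(
    jtc_two_thirds = list(x = c("v1", "v2", "v3"), y = c("v1", "v2")),
    null_dataset = generate(scenario_config(
      network = "F1N", n_samples = 8L, n_variables = 100L,
      category_probs = c(A = 1, B = 0, U = 0), dropout = 0, seed = 101L)),
    f1n_reroute = generate(scenario_config(
      network = "F1N", n_samples = 6L, n_variables = 60L, dropout = 0,
      planted_reroutes = list(list(variable = "auto", from_axis = "SH",
                                   to_axis = "SB")),
      seed = 202L))
  )
}
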