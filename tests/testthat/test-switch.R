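# A/B/U categorisation, Jaccard-Tanimoto statistics, axis comparison,
# re-routing detection and routing diagrams.

test_that("categorisation places variables by membership pattern", {
  net <- toy_chain()
  sets <- list(liver = c("all", "ls", "lb"),
               serum = c("all", "ls"),
               brain = c("all", "lb"))
  pm <- make_presence(list(`NP-NC` = sets), c("liver", "serum", "brain"))
  cat <- categorize(pm, net, "NP-NC")
  # in all three compartments -> A only
  expect_equal(cat$A, "all")
  expect_false("all" %in% unlist(cat$U))
  # liver and serum only -> B on the liver-serum axis only
  expect_equal(cat$B$LS, "ls")
  expect_false("ls" %in% unlist(cat$U))
  # liver and brain only (non-adjacent) -> U in both
  expect_true("lb" %in% cat$U$liver)
  expect_true("lb" %in% cat$U$brain)
  expect_false("lb" %in% unlist(cat$B))
})

test_that("categorisation matches a brute-force oracle on every 3-node pattern", {
  net <- toy_chain()
  comps <- net$nodes
  # every membership pattern of a single variable over three compartments
  for (mask in 1:7) {
    where <- comps[as.logical(bitwAnd(mask, c(1L, 2L, 4L)))]
    sets <- stats::setNames(lapply(comps, function(cc)
      if (cc %in% where) "v" else character(0)), comps)
    pm <- make_presence(list(ph = sets), comps)
    got <- categorize(pm, net, "ph")
    want <- brute_categorize(sets, net)
    expect_equal(got$A, want$A, info = paste("mask", mask))
    expect_equal(got$B, want$B, info = paste("mask", mask))
    expect_equal(got$U, want$U, info = paste("mask", mask))
  }
})

test_that("categorisation matches the oracle on random preset patterns", {
  set.seed(31)
  for (nm in c("F1N", "F1A", "F2N")) {
    net <- preset_network(nm)
    for (rep in 1:5) {
      sets <- random_sets(net, 25L)
      pm <- make_presence(list(ph = sets), net$nodes)
      got <- categorize(pm, net, "ph")
      want <- brute_categorize(sets, net)
      expect_equal(got$A, want$A)
      expect_equal(got$B, want$B)
      expect_equal(got$U, want$U)
    }
  }
})

test_that("Jaccard coefficient follows intersection over union", {
  expect_equal(round(jaccard(c("v1", "v2", "v3"), c("v1", "v2")), 2), 0.67)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_warning(j <- jaccard(character(0), character(0)), "undefined")
  expect_true(is.na(j))
})

test_that("Jaccard is symmetric and grows with shared variables", {
  set.seed(32)
  pool <- paste0("v", 1:12)
  for (i in 1:20) {
    x <- sample(pool, sample(1:8, 1))
    y <- sample(pool, sample(1:8, 1))
    expect_equal(jaccard(x, y), jaccard(y, x))
    extra <- paste0("new", i)
    expect_gte(jaccard(c(x, extra), c(y, extra)), jaccard(x, y))
  }
})

test_that("exact resampling p-value reproduces hand-derived cases", {
  # subset of the same universe: every redraw is at least as similar
  expect_equal(jaccard_pvalue(c("v1", "v2", "v3"), c("v1", "v2")), 1)
  # degenerate: both lists are the whole universe
  u <- c("a", "b", "c")
  expect_equal(jaccard_pvalue(u, u, u), 1)
  # two singletons in a two-element universe: J'=0 in 2 of 4 pairs
  expect_equal(jaccard_pvalue("v1", "v2", c("v1", "v2")), 0.5)
})

test_that("exact p-value agrees with full subset-pair enumeration", {
  set.seed(33)
  for (i in 1:15) {
    N <- sample(2:6, 1)
    u <- paste0("v", 1:N)
    x <- sample(u, sample(1:N, 1))
    y <- sample(u, sample(1:N, 1))
    expect_equal(jaccard_pvalue(x, y, u), brute_jaccard_pvalue(x, y, u),
                 tolerance = 1e-12)
  }
})

test_that("p-value inputs are validated", {
  expect_error(jaccard_pvalue("a", "b", universe = "a"), "subsets")
  expect_error(jaccard_pvalue("a", "b", c("a", "b"), method = "montecarlo",
                              draws = 0, seed = 1), "draws")
  expect_error(jaccard_pvalue("a", "b", c("a", "b"), method = "montecarlo",
                              draws = 10), "seed")
  expect_error(jaccard_pvalue(character(0), character(0)), "empty")
})

two_pheno_report <- function(sets_ctrl, sets_expt, net = toy_chain(),
                             include_a = TRUE) {
  pm <- make_presence(list(`NP-NC` = sets_ctrl, `LP-HC` = sets_expt),
                      net$nodes)
  switch_report(pm, net, "NP-NC", "LP-HC", include_a = include_a)
}

test_that("identical phenotypes give J = 1 and p = 1 on every axis", {
  net <- toy_chain()
  sets <- list(liver = paste0("v", 1:6), serum = paste0("v", 1:4),
               brain = paste0("v", 3:4))
  rep <- two_pheno_report(sets, sets, net)
  expect_true(all(rep$comparisons$J == 1))
  expect_true(all(rep$comparisons$p == 1))
  expect_equal(rep$comparisons$n_control, rep$comparisons$n_experimental)
})

test_that("a planted one-in-ten difference gives J = 9/11 on the axis", {
  net <- toy_chain()
  ctrl_vars <- paste0("v", 1:10)
  expt_vars <- c(paste0("v", 1:9), "v11")
  # all on the liver-serum axis, absent from brain (no A-type variables)
  sets_ctrl <- list(liver = ctrl_vars, serum = ctrl_vars,
                    brain = character(0))
  sets_expt <- list(liver = expt_vars, serum = expt_vars,
                    brain = character(0))
  rep <- two_pheno_report(sets_ctrl, sets_expt, net)
  cmp <- compare_axis(rep, "LS")
  expect_equal(cmp$n_control, 10)
  expect_equal(cmp$n_experimental, 10)
  expect_equal(cmp$J, 9 / 11)
})

test_that("an empty control axis against a non-empty one gives J = 0", {
  net <- toy_chain()
  sets_ctrl <- list(liver = "v1", serum = character(0), brain = character(0))
  sets_expt <- list(liver = c("v1", "v2"), serum = "v2", brain = character(0))
  rep <- two_pheno_report(sets_ctrl, sets_expt, net)
  expect_equal(compare_axis(rep, "LS")$J, 0)
  expect_error(compare_axis(rep, "ZZ"), "unknown axis")
})

test_that("ubiquitous variables count on every axis unless excluded", {
  net <- toy_chain()
  sets <- list(liver = c("ubi", "ls"), serum = c("ubi", "ls"),
               brain = "ubi")
  rep_a <- two_pheno_report(sets, sets, net, include_a = TRUE)
  expect_equal(rep_a$comparisons$n_control, c(2, 1))  # LS: ubi+ls, SB: ubi
  rep_b <- two_pheno_report(sets, sets, net, include_a = FALSE)
  expect_equal(rep_b$comparisons$n_control, c(1, 0))
})

test_that("re-routing detection finds exactly the moved variables", {
  net <- preset_network("F1N")
  base <- list(liver = "keep", serum = c("keep", "mv", "both"),
               brain = "both", heart = c("mv", "both"))
  moved <- list(liver = "keep", serum = c("keep", "mv", "both"),
                brain = c("mv", "both"), heart = "both")
  # identical phenotypes: nothing re-routed
  rep_same <- {
    pm <- make_presence(list(`NP-NC` = base, `LP-HC` = base), net$nodes)
    switch_report(pm, net, "NP-NC", "LP-HC")
  }
  expect_length(find_rerouted(rep_same, "SH", "SB"), 0)
  # "mv" moved from serum-heart to serum-brain; "both" travels both axes
  # in both phenotypes and is excluded
  pm <- make_presence(list(`NP-NC` = base, `LP-HC` = moved), net$nodes)
  rep <- switch_report(pm, net, "NP-NC", "LP-HC")
  expect_equal(find_rerouted(rep, "SH", "SB"), "mv")
  expect_error(find_rerouted(rep, "LS", "XX"), "unknown axis")
})

test_that("re-routing requires axes sharing an endpoint", {
  # two disjoint axes in a 4-node chain-free network
  net <- compartment_network(
    nodes = c("liver", "serum", "brain", "heart"),
    edges = data.frame(from = c("liver", "serum", "brain"),
                       to = c("serum", "brain", "heart")),
    origin = "liver", hub = "serum", termini = "brain")
  sets <- list(liver = "v", serum = "v", brain = character(0),
               heart = character(0))
  pm <- make_presence(list(a = sets, b = sets), net$nodes)
  rep <- switch_report(pm, net, "a", "b")
  lab <- axes(net)$label
  expect_error(find_rerouted(rep, lab[1], lab[3]), "share no endpoint")
})

test_that("routing diagrams list one edge per travelled axis", {
  net <- preset_network("F1N")
  sets <- list(liver = "ubi", serum = c("ubi", "sh"), brain = "ubi",
               heart = c("ubi", "sh"))
  pm <- make_presence(list(`NP-NC` = sets, `LP-HC` = sets), net$nodes)
  rep <- switch_report(pm, net, "NP-NC", "LP-HC")
  # an A-type variable travels all 3 axes of F1N, per phenotype
  d <- routing_diagram(rep, "ubi")
  expect_equal(nrow(d$edges), 6)
  expect_setequal(unique(d$edges$axis), c("LS", "SB", "SH"))
  d2 <- routing_diagram(rep, c("ubi", "sh"))
  expect_equal(sum(d2$edges$variable == "sh"), 2)  # SH in each phenotype
  expect_error(routing_diagram(rep, "ghost"), "ghost")
  # empty variable set -> empty graph
  d0 <- routing_diagram(rep, character(0))
  expect_equal(nrow(d0$edges), 0)
  expect_equal(igraph::ecount(d0$graph), 0)
  # serialisation
  for (fmt in c("dot", "graphml")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_routing(d, path, fmt)
    expect_true(file.size(path) > 0)
  }
})

test_that("the tidy switch table covers A, B and U rows", {
  net <- toy_chain()
  sets <- list(liver = c("a", "b"), serum = c("a", "b"), brain = c("a", "u"))
  pm <- make_presence(list(ph1 = sets, ph2 = sets), net$nodes)
  rep <- switch_report(pm, net, "ph1", "ph2")
  tab <- switch_report_table(rep)
  expect_setequal(unique(tab$category), c("A", "B", "U"))
  ph1 <- tab[tab$phenotype == "ph1", ]
  expect_equal(ph1$variable[ph1$category == "A"], "a")
  expect_equal(ph1$variable[ph1$category == "B"], "b")
  expect_equal(ph1$variable[ph1$category == "U"], "u")
})
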