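# CSV ingestion, per-mille signal correction and the detection rule.

wide_fixture <- function() {
  df <- data.frame(
    sample_id = c("s1", "s2"), compartment = "liver",
    phenotype = c("NP-NC", "LP-HC"),
    check.names = FALSE)
  df[["PC(34:1)"]] <- c(2, 1)
  df[["TG(52:5)"]] <- c(3, 4)
  df[["SM(34:1)"]] <- c(5, 5)
  df
}

test_that("wide and long layouts yield identical tables", {
  wide <- wide_fixture()
  wp <- tempfile(fileext = ".csv")
  utils::write.csv(wide, wp, row.names = FALSE)
  tw <- read_table(wp, layout = "wide")
  expect_equal(dim(tw$values), c(2L, 3L))
  expect_equal(tw$values["s1", "TG(52:5)"], 3)

  long <- do.call(rbind, lapply(c("PC(34:1)", "TG(52:5)", "SM(34:1)"),
    function(v) data.frame(sample_id = wide$sample_id,
                           compartment = wide$compartment,
                           phenotype = wide$phenotype,
                           variable = v, value = wide[[v]])))
  lp <- tempfile(fileext = ".csv")
  utils::write.csv(long, lp, row.names = FALSE)
  tl <- read_table(lp, layout = "long")
  expect_equal(tl$values[, colnames(tw$values)], tw$values)
  expect_equal(tl$samples$phenotype, tw$samples$phenotype)
})

test_that("ingestion rejects bad cells with informative errors", {
  wide <- wide_fixture()
  wide[["TG(52:5)"]][2] <- -1
  wp <- tempfile(fileext = ".csv")
  utils::write.csv(wide, wp, row.names = FALSE)
  expect_error(read_table(wp), "negative value.*s2.*TG\\(52:5\\)")

  long <- data.frame(sample_id = c("s1", "s1"), compartment = "liver",
                     phenotype = "NP-NC", variable = "PC(34:1)",
                     value = c(1, 2))
  lp <- tempfile(fileext = ".csv")
  utils::write.csv(long, lp, row.names = FALSE)
  expect_error(read_table(lp, layout = "long"), "duplicate")

  expect_error(read_table(tempfile(), layout = "wide"), "not found")
})

test_that("missing declared metadata columns are reported", {
  wide <- wide_fixture()
  wide$phenotype <- NULL
  wp <- tempfile(fileext = ".csv")
  utils::write.csv(wide, wp, row.names = FALSE)
  expect_error(read_table(wp), "phenotype")
})

test_that("signal correction rescales rows to per-mille", {
  samples <- data.frame(sample_id = "s1", compartment = "liver",
                        phenotype = "NP-NC")
  tab <- lta_table(matrix(c(2, 3, 5), 1, dimnames = list(NULL, c("a", "b", "c"))),
                   samples)
  cor1 <- signal_correct(tab)
  expect_equal(unname(cor1$values[1, ]), c(200, 300, 500))

  # internal standards are excluded from the denominator and dropped
  tab_is <- lta_table(matrix(c(2, 3, 5), 1,
                             dimnames = list(NULL, c("a", "b", "IS"))),
                      samples, internal_standards = "IS")
  cor2 <- signal_correct(tab_is)
  expect_equal(unname(cor2$values[1, ]), c(400, 600))
  expect_equal(colnames(cor2$values), c("a", "b"))
  expect_equal(unname(attr(cor2, "standards")[1, "IS"]), 5)

  # idempotent on corrected rows
  expect_equal(signal_correct(cor1)$values, cor1$values)

  # all-zero sample is rejected by name
  tab0 <- lta_table(matrix(c(0, 0), 1, dimnames = list(NULL, c("a", "b"))),
                    samples)
  expect_error(signal_correct(tab0), "s1.*zero total signal")
})

test_that("signal correction preserves within-row rank order", {
  set.seed(21)
  for (i in 1:10) {
    v <- matrix(stats::rexp(12), 3, 4,
                dimnames = list(NULL, paste0("v", 1:4)))
    tab <- lta_table(v, data.frame(sample_id = paste0("s", 1:3),
                                   compartment = "liver",
                                   phenotype = "NP-NC"))
    cv <- signal_correct(tab)$values
    for (r in 1:3) expect_equal(order(cv[r, ]), order(v[r, ]))
    expect_equal(unname(rowSums(cv)), rep(1000, 3))
  }
})

presence_fixture <- function(values_by_pheno) {
  # one compartment, one variable, two phenotype groups
  vals <- unlist(values_by_pheno)
  n <- length(vals)
  tab <- lta_table(
    matrix(c(vals, rep(1, n)), n, 2,
           dimnames = list(NULL, c("v", "ref"))),
    data.frame(sample_id = paste0("s", seq_len(n)),
               compartment = "liver",
               phenotype = rep(names(values_by_pheno),
                               lengths(values_by_pheno))))
  detect_presence(tab, "liver")
}

test_that("the >0 in >=50% of samples rule is applied per phenotype", {
  pm <- presence_fixture(list(`NP-NC` = c(1, 2, 3, 0), `LP-HC` = c(0, 0, 0, 0)))
  expect_true("v" %in% pm$entries[["NP-NC"]]$liver)   # 3/4 >= 0.5
  expect_false("v" %in% pm$entries[["LP-HC"]]$liver)  # 0/4
  expect_true("v" %in% pm$pooled$liver)               # either phenotype

  pm0 <- presence_fixture(list(`NP-NC` = c(0, 0, 0, 0), `LP-HC` = c(0, 0, 0, 0)))
  expect_false("v" %in% pm0$pooled$liver)

  # boundary: exactly 50% counts as present
  pm50 <- presence_fixture(list(`NP-NC` = c(1, 1, 0, 0), `LP-HC` = c(0, 0, 0, 0)))
  expect_true("v" %in% pm50$entries[["NP-NC"]]$liver)

  # odd n evaluated on the exact fraction: 2/5 absent, 3/5 present
  pm25 <- presence_fixture(list(`NP-NC` = c(1, 1, 0, 0, 0)))
  expect_false("v" %in% pm25$entries[["NP-NC"]]$liver)
  pm35 <- presence_fixture(list(`NP-NC` = c(1, 1, 1, 0, 0)))
  expect_true("v" %in% pm35$entries[["NP-NC"]]$liver)
})

test_that("presence is invariant under positive rescaling of any sample", {
  set.seed(22)
  v <- matrix(stats::rbinom(40, 1, 0.5) * stats::rexp(40), 8, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  samples <- data.frame(sample_id = paste0("s", 1:8),
                        compartment = rep(c("liver", "serum"), each = 4),
                        phenotype = rep(c("NP-NC", "LP-HC"), 4))
  pm1 <- detect_presence(lta_table(v, samples), c("liver", "serum"))
  v2 <- v * stats::runif(8, 0.1, 50)  # per-row positive rescale
  pm2 <- detect_presence(lta_table(v2, samples), c("liver", "serum"))
  expect_identical(pm1$entries, pm2$entries)
})

test_that("zero-sample (compartment, phenotype) pairs are flagged, not empty", {
  v <- matrix(1, 2, 1, dimnames = list(NULL, "v"))
  samples <- data.frame(sample_id = c("s1", "s2"), compartment = "liver",
                        phenotype = c("NP-NC", "NP-NC"))
  pm <- detect_presence(lta_table(v, samples), c("liver", "serum"))
  expect_true(nrow(pm$no_data) >= 1)
  expect_true(all(c("serum") %in% pm$no_data$compartment))
  expect_error(categorize(pm, preset_network("F1N"), "NP-NC"),
               "no samples|missing")
})

test_that("samples outside the declared network are rejected", {
  v <- matrix(1, 1, 1, dimnames = list(NULL, "v"))
  samples <- data.frame(sample_id = "s1", compartment = "kidney",
                        phenotype = "NP-NC")
  expect_error(detect_presence(lta_table(v, samples), c("liver", "serum")),
               "kidney")
})
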