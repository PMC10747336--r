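test_that("formula parsing handles explicit/implicit counts and round-trips", {
  f <- parse_formula("C22H22O10")
  expect_equal(unclass(f)[c("C", "H", "O")], c(C = 22L, H = 22L, O = 10L))
  f2 <- parse_formula("C7H13NO2")
  expect_equal(f2[["N"]], 1L)
  for (s in c("C53H86O23", "C16H12O7S", "C14H21N3O5", "H2O"))
    expect_identical(format_formula(parse_formula(s)), s)
  expect_error(parse_formula("C22Xx2"), "unsupported element")
  expect_error(parse_formula("22CH"), "malformed")
  expect_error(parse_formula(""), "non-empty")
})

test_that("monoisotopic mass is additive and matches hand-computed values", {
  expect_equal(monoisotopic_mass("H2O"), 18.01056, tolerance = 1e-4)
  # additivity over disjoint parts (glucose residue + aglycone)
  expect_equal(monoisotopic_mass("C6H10O5") + monoisotopic_mass("C16H12O5"),
               monoisotopic_mass("C22H22O10"), tolerance = 1e-10)
  # frozen-table sum computed independently: 22*12 + 22*1.00782503 +
  # 10*15.99491462
  expect_equal(monoisotopic_mass("C22H22O10"), 446.12130, tolerance = 2e-4)
})

test_that("adduct m/z reproduces published quasi-molecular ions", {
  expect_equal(ion_mz("C22H22O10", "[M+H]+"), 447.1286, tolerance = 5e-4)
  expect_equal(ion_mz("C40H64O12", "[M+FA-H]-"), 781.4380, tolerance = 5e-4)
  expect_equal(ion_mz("C46H74O17", "[M+Cl]-"), 933.4620, tolerance = 5e-4)
  expect_equal(ion_mz("C7H13NO2", "[M+H]+"), 144.1019, tolerance = 5e-4)
  expect_error(ion_mz("C6H6", "[M+Na]+"), "unsupported adduct")
})

test_that("protonated minus deprotonated m/z is twice the proton mass", {
  set.seed(1)
  for (i in 1:20) {
    f <- sprintf("C%dH%dN%dO%dS%d", sample(1:60, 1), sample(1:90, 1),
                 sample(0:3, 1), sample(0:20, 1), sample(0:2, 1))
    f <- gsub("[A-Z][a-z]?0", "", f)  # drop zero-count elements
    expect_equal(ion_mz(f, "[M+H]+") - ion_mz(f, "[M-H]-"),
                 2 * 1.0072765, tolerance = 1e-6)
  }
})

test_that("ppm error matches the published sign convention", {
  expect_equal(ppm_error(447.1269, 447.1286), -3.80, tolerance = 0.01)
  expect_equal(ppm_error(353.0884, 353.0878), 1.70, tolerance = 0.01)
  expect_identical(ppm_error(500, 500), 0)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("modification rules are self-consistent and mass-correct", {
  rules <- modification_rules()
  expected <- c(glucuronidation = 176.0321, sulfation = 79.9568,
                demethylation = -14.0157, hydroxylation = 15.9949,
                hydrogenation = 2.0157, deglycosylation = -162.0528)
  for (nm in names(expected))
    expect_equal(attr(rules[[nm]], "delta_mass"), expected[[nm]],
                 tolerance = 1e-4)
  # applying a rule then its negation returns the original formula
  f <- parse_formula("C22H22O10")
  g <- apply_modifications(f, "glucuronidation")
  back <- apply_modifications(g, list(-rules$glucuronidation))
  expect_identical(format_formula(back), format_formula(f))
  expect_error(apply_modifications("CH4", "deglycosylation"), "negative")
  expect_error(apply_modifications("CH4", "methylation"), "unknown")
})

test_that("annotation recovers published metabolite assignments", {
  parents <- plasma_parents()
  feats <- data.frame(id = c("M2", "M32"),
                      mz = c(621.1487, 347.0230),
                      ion_mode = c("-", "-"))
  ann <- annotate_features(feats, as.list(parents), top_only = TRUE)
  m2 <- ann[ann$feature_id == "M2", ]
  expect_identical(m2$parent, "calycosin-7-O-beta-d-glucoside")
  expect_identical(m2$modifications, "glucuronidation")
  expect_equal(m2$calc_mz, 621.1461, tolerance = 5e-4)
  m32 <- ann[ann$feature_id == "M32", ]
  expect_identical(m32$parent, "formononetin")
  expect_identical(m32$modifications, "sulfation")
  expect_equal(m32$calc_mz, 347.0231, tolerance = 5e-4)
})

test_that("annotation equals a brute-force enumeration oracle", {
  parents <- toy_parents()
  set.seed(42)
  mzs <- runif(12, 150, 700)
  # include two exactly-on-candidate masses so hits are guaranteed
  mzs <- c(mzs, ion_mz("C15H10O5", "[M-H]-"),
           ion_mz(apply_modifications("C16H12O4", "sulfation"), "[M-H]-"))
  feats <- data.frame(id = sprintf("F%02d", seq_along(mzs)), mz = mzs,
                      ion_mode = "-")
  ann <- annotate_features(feats, parents, tol_ppm = 25, max_depth = 2)
  for (i in seq_along(mzs)) {
    got <- ann[ann$feature_id == feats$id[i], ]
    got_keys <- sort(paste(got$parent, got$modifications, got$adduct))
    expect_identical(got_keys,
                     oracle_annotate(mzs[i], "-", parents, tol_ppm = 25,
                                     max_depth = 2))
  }
})

test_that("annotation handles empty inputs and rejects bad parameters", {
  empty <- annotate_features(data.frame(id = character(0), mz = numeric(0),
                                        ion_mode = character(0)),
                             toy_parents())
  expect_s3_class(empty, "data.frame")
  expect_identical(nrow(empty), 0L)
  expect_error(annotate_features(data.frame(id = "a", mz = 1,
                                            ion_mode = "-"),
                                 list()), "non-empty")
  expect_error(annotate_features(data.frame(id = "a", mz = 1,
                                            ion_mode = "-"),
                                 toy_parents(), tol_ppm = 0), "positive")
})

test_that("saponin fragmentation ladder reproduces the published series", {
  lad <- fragment_ladder("C53H86O23", "[M+H]+",
                         c("xylose", "deoxyhexose", "glucose", "glucose"))
  expect_equal(lad$mz[1], 1091.5633, tolerance = 5e-4)
  printed <- c(959.5186, 813.4651, 651.4084, 489.3562)
  for (k in 1:4)
    expect_lt(abs(ppm_error(printed[k], lad$mz[k + 1])), 10)
  expect_true(all(diff(lad$mz) < 0))
  # empty loss list: ladder is just the precursor ion
  solo <- fragment_ladder("C53H86O23", "[M+H]+")
  expect_identical(nrow(solo), 1L)
  expect_equal(solo$mz, lad$mz[1])
  expect_error(fragment_ladder("C6H10O5", "[M+H]+", c("glucose", "glucose")),
               "loss 2")
})

test_that("fragment matching is greedy on ppm with correct coverage", {
  lad <- fragment_ladder("C22H22O10", "[M+H]+", c("glucose", "CH3", "CO"))
  exact <- match_fragments(lad$mz, lad)
  expect_identical(exact$coverage, 1)
  expect_true(all(abs(exact$matches$ppm_error) < 1e-9))
  shifted <- match_fragments(lad$mz * (1 + 50e-6), lad, tol_ppm = 20)
  expect_identical(shifted$coverage, 0)
  # independent all-pairs greedy oracle on noisy observations
  set.seed(7)
  obs <- c(lad$mz * (1 + rnorm(4, 0, 5e-6)), runif(3, 100, 500))
  got <- match_fragments(obs, lad, tol_ppm = 20)
  pairs <- expand.grid(o = seq_along(obs), s = seq_len(nrow(lad)))
  pairs$ppm <- (obs[pairs$o] - lad$mz[pairs$s]) / lad$mz[pairs$s] * 1e6
  pairs <- pairs[abs(pairs$ppm) <= 20, ]
  pairs <- pairs[order(abs(pairs$ppm)), ]
  uo <- us <- integer(0); sel <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$o[i] %in% uo) && !(pairs$s[i] %in% us)) {
      uo <- c(uo, pairs$o[i]); us <- c(us, pairs$s[i]); sel <- c(sel, i)
    }
  }
  oracle <- pairs[sel, ]
  oracle <- oracle[order(oracle$s), ]
  expect_equal(got$matches$observed_mz, obs[oracle$o])
  expect_equal(got$matches$ladder_mz, lad$mz[oracle$s])
})
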