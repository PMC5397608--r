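test_that("anchor rules recover the planted CDR intervals", {
  for (seed in c(1, 2, 5)) {
    fx <- toy_fv(seed)
    h <- annotate_chain(fx$heavy, "H")
    l <- annotate_chain(fx$light, "L")
    expect_identical(unname(cdr_intervals(h)), unname(fx$cdr_h))
    expect_identical(unname(cdr_intervals(l)), unname(fx$cdr_l))
  }
})

test_that("region labels partition the chain and end in CONST", {
  fx <- toy_fv(3)
  h <- annotate_chain(fx$heavy, "H")
  expect_length(h$regions, nchar(fx$heavy))
  expect_identical(sum(table(h$regions)), nchar(fx$heavy))
  expect_identical(h$regions[nchar(fx$heavy)], "CONST")
  # CDRs contiguous and ordered
  idx <- lapply(c("CDR1", "CDR2", "CDR3"), function(r)
    which(h$regions == r))
  for (v in idx) expect_identical(v, seq(min(v), max(v)))
  expect_true(max(idx[[1]]) < min(idx[[2]]) && max(idx[[2]]) < min(idx[[3]]))
})

test_that("annotation is idempotent and external numbering is verbatim", {
  fx <- toy_fv(1)
  h <- annotate_chain(fx$heavy, "H")
  expect_identical(annotate_chain(h, "H"), h)

  sidecar <- data.frame(position = h$numbering$position,
                        ins = h$numbering$ins, aa = h$numbering$aa,
                        region = rev(h$regions))
  h2 <- annotate_chain(fx$heavy, "H", external_numbering = sidecar)
  expect_identical(h2$regions, rev(h$regions))
})

test_that("annotation preconditions are enforced", {
  expect_error(annotate_chain("ACDEFGHIKL", "L"), "too short")
  no_cys <- paste(rep("S", 80), collapse = "")
  expect_error(annotate_chain(no_cys, "H"), "Cys")
  # heavy chain with Cys but no WG.G motif
  seqs <- paste0(paste(rep("S", 21), collapse = ""), "C",
                 paste(rep("T", 70), collapse = ""), "C",
                 paste(rep("S", 20), collapse = ""))
  expect_error(annotate_chain(seqs, "H"), "WG.G")
})

test_that("net charge follows the K/R minus D/E convention", {
  fx <- toy_fv(1)
  l <- annotate_chain(fx$light, "L")
  mini <- l
  mini$sequence <- "KRDE"
  mini$regions <- rep("FR1", 4)
  mini$numbering <- data.frame(position = 1:4, ins = "",
                               aa = c("K", "R", "D", "E"))
  expect_equal(as.integer(net_charge(mini, "chain")), 0L)
  mini$sequence <- "KKKH"
  expect_equal(as.integer(net_charge(mini, "chain")), 3L)
  expect_equal(as.integer(net_charge(mini, "chain", his_positive = TRUE)),
               4L)
})

test_that("scoped net charges add up over the region partition", {
  for (seed in 1:4) {
    fx <- toy_fv(seed)
    h <- annotate_chain(fx$heavy, "H")
    expect_equal(as.integer(net_charge(h, "chain")),
                 as.integer(net_charge(h, "framework")) +
                   as.integer(net_charge(h, "cdr")))
  }
  # planted fixture: charges only ever land in the framework
  fx <- toy_fv(2)
  h <- annotate_chain(fx$heavy, "H")
  expect_equal(as.integer(net_charge(h, "cdr")), 0L)
  aa <- strsplit(fx$heavy, "")[[1]]
  hand <- sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
  expect_equal(as.integer(net_charge(h, "framework")), hand)
})

test_that("APR interval labels follow the CDR-overlap rule", {
  fx <- toy_fv(1)
  h <- annotate_chain(fx$heavy, "H")
  fr3 <- range(which(h$regions == "FR3"))
  expect_identical(apr_region_label(h, c(fr3[1] + 2, fr3[1] + 6)), "FR")
  # spanning the FR2/CDR2 boundary labels by the CDR
  c2 <- range(which(h$regions == "CDR2"))
  expect_identical(apr_region_label(h, c(c2[1] - 3, c2[1] + 1)), "CDR2")
  # touching two CDRs is mixed
  c1 <- range(which(h$regions == "CDR1"))
  expect_identical(apr_region_label(h, c(c1[2], c2[1])), "mixed")
  expect_error(apr_region_label(h, c(10, 5)), "interval")
  expect_error(apr_region_label(h, c(0, 5)), "outside")
})
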