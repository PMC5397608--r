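test_that("gatekeeper scans enumerate five mutations per APR position", {
  fit <- toy_fit(1)                       # planted 6-residue APR
  ms <- mass_scan(fit, "H", 1)
  expect_equal(nrow(ms), 30L)
  expect_true(all(ms$mut %in% c("D", "E", "K", "R", "P")))
  expect_true(all(ms$d_tango <= 0))
  # sorted by suppression first
  expect_true(!is.unsorted(ms$d_tango))
})

test_that("positions already holding a gatekeeper are skipped", {
  fit <- toy_fit(2)
  # force one APR position to lysine in the annotated sequence
  apr <- c(fit$points$start[1], fit$points$end[1])
  substr(fit$chains$H$sequence, apr[1] + 1, apr[1] + 1) <- "K"
  ms <- mass_scan(fit, "H", 1)
  expect_equal(nrow(ms), 5L * (apr[2] - apr[1] + 1L) - 1L)
  expect_false(any(ms$position == apr[1] + 1 & ms$mut == "K"))
})

test_that("shortlisting filters on stability and ranks by suppression", {
  cand <- data.frame(chain = "H", position = c(1, 2, 3, 4), ins = "",
                     wt = "I", mut = c("D", "E", "K", "R"),
                     d_tango = c(-90, -60, -60, -10),
                     ddg = c(2.0, 0.2, 0.1, -1), d_charge = 0L)
  sel <- select_mass_candidates(cand, max_ddg = 0.5)
  expect_equal(nrow(sel), 3L)                    # the +2.0 one is dropped
  expect_equal(sel$position[1:2], c(3, 2))       # tie on d_tango: lower ddg
  sel2 <- select_mass_candidates(cand, max_ddg = 0.5, top_n = 2)
  expect_equal(nrow(sel2), 2L)
  expect_warning(none <- select_mass_candidates(cand, max_ddg = -5),
                 "exceed")
  expect_equal(nrow(none), 0L)
  expect_error(select_mass_candidates(cand[0, ]), "no candidates")
})

test_that("supercharge alphabet matches the hand enumeration on ASD", {
  ch <- structure(list(chain_type = "H", sequence = "ASD",
                       numbering = data.frame(position = 1:3, ins = "",
                                              aa = c("A", "S", "D")),
                       regions = rep("FR1", 3)),
                  class = "antibody_chain")
  fit <- structure(list(chains = list(H = ch), mode = "sequence-only"),
                   class = c("solubis", "solubis_report"))
  sc <- supercharge_scan(fit)
  expect_equal(nrow(sc), 8L)
  got <- sort(paste0(sc$wt, sc$position, sc$mut))
  expect_equal(got, sort(c("A1K", "A1R", "S2K", "S2R",
                           "D3K", "D3R", "D3N", "D3Q")))
  expect_equal(sc$d_charge[sc$wt == "D" & sc$mut == "K"], 2L)
  # all-K segment yields nothing
  ch$sequence <- "KKK"
  ch$numbering$aa <- c("K", "K", "K")
  fit$chains$H <- ch
  expect_equal(nrow(supercharge_scan(fit)), 0L)
})

test_that("supercharge candidates avoid CDRs and raise the net charge", {
  fit <- toy_fit(1)
  sc <- supercharge_scan(fit)
  h <- fit$chains$H
  reg <- h$regions[match(sc$position, h$numbering$position)]
  expect_false(any(grepl("^CDR", reg)))
  base <- as.integer(net_charge(h, "framework"))
  set.seed(9)
  for (k in sample(nrow(sc), 20)) {
    v <- compose_variant(fit, list(paste0(sc$wt[k], "H", sc$position[k],
                                          sc$mut[k])))
    expect_gte(v$d_charge, 1L)
  }
})

test_that("variants recompose, rescore, and validate their mutations", {
  fit <- toy_fit(1)
  wtv <- compose_variant(fit, list())
  expect_equal(wtv$report$solubis_score, fit$solubis_score)
  expect_equal(wtv$d_charge, 0L)

  apr <- c(fit$points$start[1], fit$points$end[1])
  centre <- apr[1] + 2
  wt_aa <- substr(fit$chains$H$sequence, centre, centre)
  m <- paste0(wt_aa, "H", centre, "P")
  v <- compose_variant(fit, list(m))
  expect_lt(v$report$solubis_score, fit$solubis_score)

  # wild-type letter must match
  expect_error(compose_variant(fit, list(paste0("W", "H", centre, "P"))),
               "mismatch")
  # duplicated positions rejected
  expect_error(compose_variant(fit, list(m, paste0(wt_aa, "H", centre,
                                                   "D"))),
               "duplicated")
})

test_that("variant composition is order-independent", {
  fit <- toy_fit(1)
  apr <- c(fit$points$start[1], fit$points$end[1])
  a1 <- substr(fit$chains$H$sequence, apr[1], apr[1])
  a2 <- substr(fit$chains$H$sequence, apr[1] + 3, apr[1] + 3)
  m1 <- paste0(a1, "H", apr[1], "D")
  m2 <- paste0(a2, "H", apr[1] + 3, "R")
  v12 <- compose_variant(fit, list(m1, m2))
  v21 <- compose_variant(fit, list(m2, m1))
  expect_equal(v12$report$solubis_score, v21$report$solubis_score)
  expect_equal(v12$report$points, v21$report$points)
  expect_equal(v12$d_charge, v21$d_charge)
})
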