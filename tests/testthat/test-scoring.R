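test_that("stability weights clip the summed delta-G at +/- 5", {
  expect_equal(stability_weight(-5), 0)
  expect_equal(stability_weight(0), 0.5)
  expect_equal(stability_weight(5), 1)
  expect_equal(stability_weight(7), 1)
  expect_equal(stability_weight(-12), 0)
  expect_equal(stability_weight(c(-10, 2.5)), c(0, 0.75))
  expect_error(stability_weight(NaN), "finite")
  expect_error(stability_weight(Inf), "finite")
})

fake_aprs <- function(tango) {
  n <- length(tango)
  structure(data.frame(start = seq(1, by = 10, length.out = n),
                       end = seq(6, by = 10, length.out = n),
                       sequence = rep(strrep("I", 6), n), tango_sum = tango),
            class = c("apr_set", "data.frame"))
}

test_that("stretch points combine score, weight, and criticality", {
  pts <- make_stretch_points(fake_aprs(c(100, 200, 40)), c(-5, 0, 5))
  expect_equal(pts$corrected_score, c(0, 100, 40))
  expect_equal(pts$weight, c(0, 0.5, 1))
  expect_equal(pts$critical, c(FALSE, TRUE, FALSE))
  expect_true(all(pts$corrected_score >= 0 &
                    pts$corrected_score <= pts$tango_sum))
  expect_error(make_stretch_points(fake_aprs(c(1, 2)), 0), "one dg_contrib")
  expect_error(make_stretch_points(fake_aprs(1), NaN), "finite")
})

test_that("the total score sums corrected scores exactly", {
  pts <- make_stretch_points(fake_aprs(c(100, 200, 600)), c(-5, 0, 0))
  rep <- solubis_score(pts, id = "x")
  expect_equal(rep$solubis_score, 0 + 100 + 300)
  expect_equal(rep$n_aprs, 3L)
  expect_equal(rep$total_tango, 900)
  empty <- make_stretch_points(fake_aprs(numeric(0)), numeric(0))
  expect_equal(solubis_score(empty)$solubis_score, 0)
  # thermodynamically protected APRs contribute nothing
  prot <- make_stretch_points(fake_aprs(c(500, 900)), c(-5, -8))
  expect_equal(solubis_score(prot)$solubis_score, 0)
})

test_that("scores match a hand-rolled oracle on random stretch sets", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(1:8, 1)
    tango <- stats::runif(n, 0, 400)
    dg <- stats::runif(n, -12, 12)
    got <- solubis_score(make_stretch_points(fake_aprs(tango), dg))
    oracle <- sum(tango * pmin(1, pmax(0, (dg + 5) / 10)))
    expect_equal(got$solubis_score, oracle)
    expect_gte(got$solubis_score, 0)
    expect_lte(got$solubis_score, sum(tango))
  }
})

test_that("the score is monotone in stability and order-free", {
  set.seed(22)
  tango <- stats::runif(5, 0, 300)
  dg <- stats::runif(5, -8, 8)
  base <- solubis_score(make_stretch_points(fake_aprs(tango), dg))
  for (k in 1:5) {
    dg2 <- dg; dg2[k] <- dg2[k] - stats::runif(1, 0, 5)
    lower <- solubis_score(make_stretch_points(fake_aprs(tango), dg2))
    expect_lte(lower$solubis_score, base$solubis_score)
    tg2 <- tango; tg2[k] <- tg2[k] * 0.5
    lower2 <- solubis_score(make_stretch_points(fake_aprs(tg2), dg))
    expect_lte(lower2$solubis_score, base$solubis_score)
  }
  perm <- sample(5)
  shuffled <- solubis_score(make_stretch_points(fake_aprs(tango[perm]),
                                                dg[perm]))
  expect_equal(shuffled$solubis_score, base$solubis_score)
})

test_that("stretch densities bin correctly and marginalize", {
  one <- make_stretch_points(fake_aprs(75), 0)
  d <- stretch_density(one)
  expect_equal(sum(d$count), 1)
  expect_equal(sum(d$count > 0), 1)
  hit <- d[d$count > 0, ]
  expect_true(hit$dg_low <= 0 && 0 <= hit$dg_high)

  set.seed(5)
  many <- make_stretch_points(fake_aprs(stats::runif(200, 0, 590)),
                              stats::runif(200, -14, 14))
  dd <- stretch_density(many)
  expect_equal(sum(dd$count), 200)
  marg <- tapply(dd$count, dd$dg_low, sum)
  hist1d <- table(cut(many$dg_contrib, seq(-15, 15, by = 2.5),
                      include.lowest = TRUE))
  expect_equal(as.numeric(marg), as.numeric(hist1d))
  expect_error(stretch_density(many[0, ]), "no stretch points")
})
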