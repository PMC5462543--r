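watched <- function() {
  tax <- default_taxonomy()
  list(diatoms = tax$ochrophyte_groups$diatoms,
       hypogyristea = tax$ochrophyte_groups$hypogyristea,
       chrysista = tax$ochrophyte_groups$chrysista,
       haptophytes = c("pavlovophytes", "prymnesiales", "isochrysidales"),
       cryptomonads = c("pyrenomonadales", "cryptomonadales"))
}

pres_matrix <- function(rows) {
  subs <- unlist(watched(), use.names = FALSE)
  m <- matrix(0L, nrow = length(rows), ncol = length(subs),
              dimnames = list(NULL, subs))
  for (i in seq_along(rows)) m[i, rows[[i]]] <- 1L
  m
}

test_that("uniquely shared counting enforces the exactly-two-lineage rule", {
  ls <- watched()
  m <- pres_matrix(list(
    c("pavlovophytes", "prymnesiales", "pelagophytes"),       # counted
    c("pavlovophytes", "prymnesiales", "pelagophytes", "pennates"), # 3 lin
    c("pavlovophytes", "pelagophytes")))                      # hapto minority
  expect_equal(count_unique_shared(m, c("haptophytes", "hypogyristea"),
                                   "majority+any", ls), 1L)
  # majority+majority needs 2/3 of hypogyristean sub-categories too
  m2 <- pres_matrix(list(
    c("pavlovophytes", "prymnesiales", "pelagophytes", "dictyochophytes"),
    c("pavlovophytes", "prymnesiales", "pelagophytes")))
  expect_equal(count_unique_shared(m2, c("haptophytes", "hypogyristea"),
                                   "majority+majority", ls), 1L)
})

test_that("uniquely shared counts equal an exhaustive row scan", {
  set.seed(41)
  ls <- watched()
  subs <- unlist(ls, use.names = FALSE)
  m <- matrix(rbinom(30 * length(subs), 1L, 0.3), nrow = 30,
              dimnames = list(NULL, subs))
  for (pair in list(c("haptophytes", "hypogyristea"),
                    c("haptophytes", "diatoms"),
                    c("hypogyristea", "chrysista"))) {
    mine <- count_unique_shared(m, pair, "majority+any", ls)
    oracle <- 0L
    for (i in seq_len(nrow(m))) {
      present <- vapply(ls, function(s) any(m[i, s] >= 1L), TRUE)
      k1 <- sum(m[i, ls[[pair[1L]]]] >= 1L)
      n1 <- length(ls[[pair[1L]]])
      ok <- sum(present) == 2L && present[[pair[1L]]] &&
        present[[pair[2L]]] && k1 >= (n1 %/% 2L + 1L)
      if (ok) oracle <- oracle + 1L
    }
    expect_equal(mine, oracle)
  }
})

test_that("the expectation correction reproduces the published arithmetic", {
  # involvement proportions one-half each: quarter scaled by four-thirds
  expect_equal(expected_pair_fraction(1 / 2, 1 / 2), 1 / 3)
  # symmetric three-lineage design: each pair expects one-third
  cnt <- data.frame(lineage_a = c("A", "A", "B"),
                    lineage_b = c("B", "C", "C"), count = c(10, 10, 10),
                    stringsAsFactors = FALSE)
  out <- expected_unique_shared(cnt)
  expect_equal(out$expected, rep(10, 3))
  # conservation: corrected expectations sum to the observed total
  set.seed(2)
  cnt2 <- data.frame(
    lineage_a = c("A", "A", "A", "B", "B", "C"),
    lineage_b = c("B", "C", "D", "C", "D", "D"),
    count = rpois(6, 8) + 1L, stringsAsFactors = FALSE)
  out2 <- expected_unique_shared(cnt2)
  expect_equal(sum(out2$expected), sum(cnt2$count))
  expect_error(expected_unique_shared(
    data.frame(lineage_a = "A", lineage_b = "A", count = 3)), "cross pairs")
})

test_that("the two-cell goodness-of-fit statistic matches hand computation", {
  r0 <- chi_squared_obs_exp(10, 10, 100)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  r <- chi_squared_obs_exp(15, 5, 100)
  expect_equal(r$statistic, 100 / 5 + 100 / 95, tolerance = 1e-12)
  expect_equal(r$p, stats::pchisq(r$statistic, 1, lower.tail = FALSE))
  # p decreases as the observed count moves away from expectation
  ps <- vapply(c(6, 8, 12, 20, 30),
               function(o) chi_squared_obs_exp(o, 5, 100)$p, 0)
  expect_true(all(diff(ps[3:5]) < 0))
  expect_error(chi_squared_obs_exp(10, 20, 15), "total")
})

test_that("targeting enrichment uses proportional expectations", {
  fams <- data.frame(
    origin = c(rep("red_algae", 10), rep("host", 90)),
    plastid = c(rep(TRUE, 3), rep(FALSE, 7),
                rep(TRUE, 27), rep(FALSE, 63)),
    stringsAsFactors = FALSE)
  enr <- targeting_enrichment(fams)
  expect_equal(enr$expected[enr$origin == "red_algae"], 3)
  # expectations sum exactly to the plastid-targeted total
  expect_equal(sum(enr$expected), sum(fams$plastid))

  # planted enrichment: red and green flagged, host not
  set.seed(4)
  n <- c(red_algae = 150, green_algae = 120, host = 330)
  p <- c(red_algae = 0.45, green_algae = 0.4, host = 0.12)
  fams2 <- do.call(rbind, lapply(names(n), function(o) data.frame(
    origin = o, plastid = runif(n[[o]]) < p[[o]], stringsAsFactors = FALSE)))
  enr2 <- targeting_enrichment(fams2)
  expect_true(enr2$significant[enr2$origin == "red_algae"])
  expect_true(enr2$significant[enr2$origin == "green_algae"])
  expect_false(enr2$significant[enr2$origin == "host"] &&
                 enr2$observed[enr2$origin == "host"] >
                   enr2$expected[enr2$origin == "host"])

  # null: no origin flagged at alpha 0.05 in >= 95% of seeds
  flagged <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    f <- do.call(rbind, lapply(names(n), function(o) data.frame(
      origin = o, plastid = runif(n[[o]]) < 0.25,
      stringsAsFactors = FALSE)))
    any(targeting_enrichment(f)$significant, na.rm = TRUE)
  }, TRUE)
  expect_gte(mean(!flagged), 0.75)
})

test_that("category enrichment flags departures from background proportions", {
  bg <- c(photosynthesis = 100, translation = 100, signalling = 100,
          transport = 100)
  sub_null <- c(photosynthesis = 20, translation = 20, signalling = 20,
                transport = 20)
  expect_false(any(category_enrichment(sub_null, bg)$significant))
  sub_hot <- c(photosynthesis = 60, translation = 20, signalling = 10,
               transport = 10)
  res <- category_enrichment(sub_hot, bg)
  expect_true(res$significant[res$category == "photosynthesis"])
  # invariance under permutation of category order
  perm <- rev(names(sub_hot))
  res2 <- category_enrichment(sub_hot[perm], bg[perm])
  expect_setequal(res$category[res$significant],
                  res2$category[res2$significant])
  expect_message(category_enrichment(c(sub_hot, novel = 5), bg), "skipped")
})

test_that("neighbour concordance matches enumeration and simulation", {
  # all proteins the same origin: observed equals expected, statistic 0
  om <- stats::setNames(rep("red", 6), paste0("p", 1:6))
  pairs <- data.frame(a = paste0("p", 1:3), b = paste0("p", 4:6),
                      stringsAsFactors = FALSE)
  r <- neighbour_origin_concordance(pairs, om)
  expect_equal(r$statistic, 0)
  expect_equal(r$observed, r$expected)

  # six-pair fixture against hand computation
  om2 <- stats::setNames(c("red", "red", "green", "green", "red", "green"),
                         paste0("q", 1:6))
  pairs2 <- data.frame(a = c("q1", "q1", "q3", "q5", "q2", "q4"),
                       b = c("q2", "q3", "q4", "q6", "q5", "q6"),
                       stringsAsFactors = FALSE)
  r2 <- neighbour_origin_concordance(pairs2, om2)
  q <- table(c(om2[pairs2$a], om2[pairs2$b])) / 12
  expect_equal(r2$observed, 4)
  expect_equal(r2$expected, 6 * sum(q^2))

  # two origins at 50/50 with random pairing: observed/expected ratio -> 1
  set.seed(9)
  om3 <- stats::setNames(sample(c("red", "green"), 400, replace = TRUE),
                         paste0("g", 1:400))
  pairs3 <- data.frame(a = paste0("g", sample(400, 1000, TRUE)),
                       b = paste0("g", sample(400, 1000, TRUE)),
                       stringsAsFactors = FALSE)
  pairs3 <- pairs3[pairs3$a != pairs3$b, ]
  r3 <- neighbour_origin_concordance(pairs3, om3)
  expect_lt(abs(r3$observed / r3$expected - 1), 0.15)
})

test_that("coexpression summaries behave on identical and null profiles", {
  set.seed(12)
  expr <- matrix(rnorm(20 * 30), nrow = 20,
                 dimnames = list(paste0("g", 1:20), NULL))
  expr[2, ] <- expr[1, ] # identical profiles correlate at 1
  origin <- stats::setNames(rep(c("red", "green"), each = 10),
                            rownames(expr))
  res <- coexpression_by_origin(expr, origin)
  r12 <- res$correlations$r[res$correlations$gene_a == "g1" &
                              res$correlations$gene_b == "g2"]
  expect_equal(r12, 1)
  # symmetric with unit diagonal by construction of the pair list
  expect_true(all(res$correlations$gene_a != res$correlations$gene_b))
  expect_true(all(abs(res$correlations$r) <= 1))
  # constant vectors are excluded
  expr2 <- expr; expr2[3, ] <- 5
  expect_message(coexpression_by_origin(expr2, origin), "constant")
})
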