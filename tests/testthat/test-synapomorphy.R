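test_that("vertical-inheritance screening counts separated lineage clades", {
  tax <- default_taxonomy()
  # one red clade, one green clade: include
  t1 <- ape::read.tree(text = paste0(
    "((cyanidiales|r1|f,florideophytes|r2|f),",
    "(core_chlorophytes|g1|f,prasinophytes|g2|f),",
    "(pennates|o1|f,corethron|o2|f));"))
  expect_true(screen_vertical_inheritance(annotate_tree(t1, tax))$include)

  # two red clades separated by two green leaves: exclude, offender red
  t2 <- ape::read.tree(text = paste0(
    "(((cyanidiales|r1|f,florideophytes|r2|f),",
    "(core_chlorophytes|g1|f,prasinophytes|g2|f)),",
    "(porphyridiophytes|r3|f,cyanidiales|r4|f),",
    "(pennates|o1|f,corethron|o2|f));"))
  r2 <- screen_vertical_inheritance(annotate_tree(t2, tax))
  expect_false(r2$include)
  expect_true("red_algae" %in% r2$offending_lineages)

  # a green clade containing a nested ochrophyte clade: allowance holds
  t3 <- ape::read.tree(text = paste0(
    "(((core_chlorophytes|g1|f,(pennates|o1|f,corethron|o2|f)),",
    "prasinophytes|g2|f),(cyanidiales|r1|f,florideophytes|r2|f),",
    "(oomycetes|s1|f,labyrinthulomycetes|s2|f));"))
  expect_true(screen_vertical_inheritance(annotate_tree(t3, tax))$include)
})

test_that("member validation applies the two-stage composite rules", {
  tax <- default_taxonomy()
  aln_subs <- c("cyanidiales", "florideophytes", "core_chlorophytes",
                "pennates")
  keep <- validate_member_sequence(
    "cyanidiales", c("cyanidiales", "florideophytes", "porphyridiophytes"),
    data.frame(sub_category = c("florideophytes", "core_chlorophytes"),
               evalue = c(1e-50, 1e-20), stringsAsFactors = FALSE),
    aln_subs, tax)
  expect_true(keep$keep)

  drop <- validate_member_sequence(
    "cyanidiales", c("core_chlorophytes", "cyanidiales", "cyanidiales"),
    data.frame(sub_category = "florideophytes", evalue = 1e-50,
               stringsAsFactors = FALSE), aln_subs, tax)
  expect_false(drop$keep)
  expect_equal(drop$reason, "global lineage")

  # glaucophyte whose alignment top hit is cyanobacterial: allowance
  gl <- validate_member_sequence(
    "glaucophytes_sc", rep("glaucophytes_sc", 3),
    data.frame(sub_category = "cyanobacteria", evalue = 1e-30,
               stringsAsFactors = FALSE),
    c("glaucophytes_sc", "cyanobacteria"), tax)
  expect_true(gl$keep)

  # green query hitting ochrophytes first is kept only with stronger green
  # than red support
  g1 <- validate_member_sequence(
    "core_chlorophytes", rep("core_chlorophytes", 3),
    data.frame(sub_category = c("pennates", "prasinophytes", "cyanidiales"),
               evalue = c(1e-60, 1e-50, 1e-40), stringsAsFactors = FALSE),
    c("core_chlorophytes", "prasinophytes", "pennates", "cyanidiales"), tax)
  expect_true(g1$keep)
  g2 <- validate_member_sequence(
    "core_chlorophytes", rep("core_chlorophytes", 3),
    data.frame(sub_category = c("pennates", "cyanidiales", "prasinophytes"),
               evalue = c(1e-60, 1e-50, 1e-40), stringsAsFactors = FALSE),
    c("core_chlorophytes", "prasinophytes", "pennates", "cyanidiales"), tax)
  expect_false(g2$keep)

  # same-sub-category fallback when no other sub-category exists
  fb <- validate_member_sequence(
    "opisthokonts", rep("opisthokonts", 3),
    data.frame(sub_category = "opisthokonts", evalue = 1e-30,
               stringsAsFactors = FALSE),
    c("opisthokonts", "pennates"), tax)
  expect_true(fb$keep)
})

test_that("uniquely shared residues follow the four clauses", {
  aln <- rbind(
    f1 = c("A", "A", "G"), f2 = c("A", "A", "A"), f3 = c("A", "A", "A"),
    d1 = c("A", "A", "A"), d2 = c("-", "-", "-"),
    e1 = c("G", "-", "S"), e2 = c("G", "-", "-"))
  res <- find_unique_shared_residues(aln, c("f1", "f2", "f3"),
                                     c("d1", "d2"), c("e1", "e2"))
  # column 0: focal all A, donor A, exclusion G (ungapped, different): hit
  expect_true(0L %in% res$column)
  # column 1: every exclusion sequence gapped: clause (d) fails
  expect_false(1L %in% res$column)
  # column 2: 2/3 of focal share A, donor A, exclusion S: hit
  expect_true(2L %in% res$column)
  expect_equal(res$focal_share_fraction[res$column == 2L], 2 / 3)
})

test_that("the column scan equals exhaustive per-column enumeration", {
  set.seed(31)
  for (rep in 1:100) {
    nf <- sample(3:6, 1); nd <- sample(1:3, 1); ne <- sample(1:3, 1)
    ncol_ <- sample(10:50, 1)
    mk <- function(n, prefix) {
      m <- matrix(sample(c("A", "G", "S", "T", "-"), n * ncol_,
                         replace = TRUE, prob = c(.3, .25, .2, .15, .1)),
                  nrow = n)
      rownames(m) <- paste0(prefix, seq_len(n))
      m
    }
    aln <- rbind(mk(nf, "f"), mk(nd, "d"), mk(ne, "e"))
    mine <- find_unique_shared_residues(
      aln, paste0("f", 1:nf), paste0("d", 1:nd), paste0("e", 1:ne))
    oracle <- oracle_unique_shared(
      aln, paste0("f", 1:nf), paste0("d", 1:nd), paste0("e", 1:ne))
    expect_equal(mine$column,
                 as.integer(vapply(oracle, function(h) h["col"], "")))
  }
})

test_that("origin nodes follow the matching-majority rule in both modes", {
  ref <- ape::read.tree(
    text = "(((a,b)ab,(c,d)cd)abcd,(e,f)ef)root;")
  # matching in all of a-d, absent in e,f -> abcd ancestor
  s1 <- c(a = "match", b = "match", c = "match", d = "match",
          e = "mismatch", f = "mismatch")
  expect_equal(infer_origin_node(s1, ref, "observed"), "abcd")
  # residue in one sub-category only -> that leaf
  s2 <- c(a = "match", b = "mismatch", c = "mismatch", d = "mismatch",
          e = "mismatch", f = "mismatch")
  expect_equal(infer_origin_node(s2, ref, "observed"), "a")
  # 2 matches + 2 gaps in a 4-leaf clade: observed fails, earliest passes
  s3 <- c(a = "match", b = "match", c = "gap", d = "gap",
          e = "mismatch", f = "mismatch")
  expect_equal(infer_origin_node(s3, ref, "observed"), "ab")
  expect_equal(infer_origin_node(s3, ref, "earliest",
                                 observed_node = "ab"), "abcd")
})

test_that("earliest origin nodes are ancestral-or-equal to observed ones", {
  ref <- reference_green_topology()
  set.seed(13)
  depth <- function(tr, label) {
    all_labels <- c(tr$tip.label, tr$node.label)
    nd <- match(label, all_labels)
    d <- 0L
    repeat {
      up <- tr$edge[tr$edge[, 2L] == nd, 1L]
      if (!length(up)) break
      nd <- up; d <- d + 1L
    }
    d
  }
  for (i in 1:200) {
    status <- stats::setNames(
      sample(c("match", "mismatch", "gap"), length(ref$tip.label),
             replace = TRUE), ref$tip.label)
    if (!any(status == "match")) next
    obs <- infer_origin_node(status, ref, "observed")
    ear <- infer_origin_node(status, ref, "earliest", observed_node = obs)
    if (is.na(obs) || is.na(ear)) next
    expect_lte(depth(ref, ear), depth(ref, obs))
  }
})

test_that("composition bias is flagged by the per-residue chi-squared", {
  set.seed(8)
  n <- 2000
  a <- sample(c("G", "A", "L"), n, replace = TRUE, prob = c(0.02, 0.5, 0.48))
  b <- sample(c("G", "A", "L"), n, replace = TRUE, prob = c(0.08, 0.47, 0.45))
  aln <- rbind(A1 = a, B1 = b)
  res <- composition_bias_filter(aln, "A1", "B1")
  expect_true("G" %in% res$flagged)
  expect_false(any(res$alignment %in% res$flagged))
  # identical composition: no flags
  res2 <- composition_bias_filter(rbind(A1 = a, B1 = a), "A1", "B1")
  expect_equal(res2$flagged, character(0))
  # the glycine statistic matches the hand-computed 2x2 chi-squared
  tab <- rbind(c(sum(a == "G"), sum(a != "G")),
               c(sum(b == "G"), sum(b != "G")))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - E)^2 / E)
  expect_equal(res$tests$statistic[res$tests$residue == "G"], hand,
               tolerance = 1e-10)
})

test_that("concatenated shared-residue counts match a brute-force scan", {
  aln <- rbind(
    h1 = c("A", "A", "G", "T"), h2 = c("A", "A", "G", "T"),
    h3 = c("A", "A", "G", "-"),
    c1 = c("A", "G", "G", "T"),
    r1 = c("G", "A", "S", "S"), r2 = c("G", "G", "S", "S"))
  partners <- list(cryptomonads = "c1", red_algae = c("r1", "r2"))
  # strict: col 1 shared with cryptomonads only; col 2 with red only via A?
  strict <- count_shared_residues_concatenated(
    aln, c("h1", "h2", "h3"), partners, "strict")
  expect_equal(unname(strict["cryptomonads"]), 2L) # columns 1 and 3
  expect_equal(unname(strict["red_algae"]), 1L)    # column 2
  maj <- count_shared_residues_concatenated(
    aln, c("h1", "h2", "h3"), partners, "majority", majority_count = 2L)
  # column 4 now qualifies (T in 2 of 3 focal, unique to cryptomonads)
  expect_equal(unname(maj["cryptomonads"]), 3L)

  # random alignments against an exhaustive per-column oracle
  set.seed(17)
  for (rep in 1:50) {
    ncol_ <- 50
    mk <- function(n) matrix(sample(c("A", "G", "T", "-"), n * ncol_,
                                    replace = TRUE), nrow = n)
    aln2 <- rbind(mk(4), mk(2), mk(3))
    rownames(aln2) <- c(paste0("h", 1:4), paste0("x", 1:2), paste0("y", 1:3))
    partners2 <- list(X = paste0("x", 1:2), Y = paste0("y", 1:3))
    mine <- count_shared_residues_concatenated(aln2, paste0("h", 1:4),
                                               partners2, "strict")
    oracle <- c(X = 0L, Y = 0L)
    for (j in seq_len(ncol_)) {
      f <- aln2[paste0("h", 1:4), j]
      if (any(f == "-") || length(unique(f)) != 1L) next
      r <- f[1L]
      inX <- any(aln2[partners2$X, j] == r)
      inY <- any(aln2[partners2$Y, j] == r)
      if (inX && !inY) oracle["X"] <- oracle["X"] + 1L
      if (inY && !inX) oracle["Y"] <- oracle["Y"] + 1L
    }
    expect_equal(mine, oracle)
  }
})
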