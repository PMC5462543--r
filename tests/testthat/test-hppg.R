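mk_ht <- function(df) {
  df$pident <- 50; df$qstart <- 0L; df$qend <- 100L
  df$sstart <- 0L; df$send <- 100L
  hit_table(df)
}

test_that("the outgroup cap is the rank-1 outgroup hit, open when absent", {
  lin <- c(s_red = "red_algae", s_red2 = "red_algae", s_och = "ochrophytes")
  h <- mk_ht(data.frame(query_id = "seed",
                        subject_id = c("s_och", "s_red", "s_red2"),
                        evalue = c(1e-50, 1e-30, 1e-10),
                        bitscore = c(200, 120, 60),
                        stringsAsFactors = FALSE))
  cap <- compute_outgroup_cap("seed", h, lin)
  expect_equal(cap$evalue, 1e-30) # rank-1 outgroup hit, not 1e-10
  expect_equal(cap$rank, 2L)
  expect_false(cap$open)

  h2 <- mk_ht(data.frame(query_id = "seed", subject_id = "s_och",
                         evalue = 1e-50, bitscore = 200,
                         stringsAsFactors = FALSE))
  cap2 <- compute_outgroup_cap("seed", h2, lin)
  expect_true(cap2$open)
})

test_that("seed merging follows strict caps, zero-zero rank ties and precedence", {
  cands <- data.frame(seq_id = c("a", "b", "c"),
                      species_id = c("sp2", "sp1", "sp3"),
                      stringsAsFactors = FALSE)
  caps <- list(
    a = structure(list(seed_id = "a", evalue = 1e-30, bitscore = 100,
                       rank = 3L, open = FALSE), class = "outgroup_cap"),
    b = structure(list(seed_id = "b", evalue = 1e-30, bitscore = 100,
                       rank = 3L, open = FALSE), class = "outgroup_cap"),
    c = structure(list(seed_id = "c", evalue = 1e-30, bitscore = 100,
                       rank = 3L, open = FALSE), class = "outgroup_cap"))
  # a-b admissible (1e-50 < 1e-30); a-c not (1e-20 >= 1e-30)
  h <- mk_ht(data.frame(
    query_id = c("a", "a"), subject_id = c("b", "c"),
    evalue = c(1e-50, 1e-20), bitscore = c(200, 80),
    stringsAsFactors = FALSE))
  res <- merge_seeds(cands, h, caps, c("sp1", "sp2", "sp3"))
  expect_equal(unname(res$merge_map[c("a", "b")]), c("b", "b")) # sp1 first
  expect_equal(unname(res$merge_map["c"]), "c")

  # zero-zero tie: admissible only when the hit ranks before the outgroup hit
  h0 <- mk_ht(data.frame(query_id = "a", subject_id = c("b", "c"),
                         evalue = c(0, 0), bitscore = c(500, 300),
                         stringsAsFactors = FALSE))
  caps0 <- caps
  caps0$a$evalue <- 0; caps0$a$rank <- 2L
  res0 <- merge_seeds(cands, h0, caps0, c("sp1", "sp2", "sp3"))
  expect_equal(unname(res0$merge_map["a"]), unname(res0$merge_map["b"]))
  expect_false(res0$merge_map["c"] == res0$merge_map["a"])

  expect_error(merge_seeds(cands, h, caps, c("sp1", "sp1")), "cyclic")
})

test_that("transitive closure of admissible matches equals a brute-force oracle", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(5:20, 1L)
    ids <- sprintf("s%02d", seq_len(n))
    cands <- data.frame(seq_id = ids, species_id = ids,
                        stringsAsFactors = FALSE)
    caps <- lapply(ids, function(i)
      structure(list(seed_id = i, evalue = 10^-runif(1, 5, 40),
                     bitscore = 100, rank = 99L, open = FALSE),
                class = "outgroup_cap"))
    names(caps) <- ids
    npairs <- sample(3:25, 1L)
    qi <- sample(n, npairs, replace = TRUE)
    si <- sample(n, npairs, replace = TRUE)
    keep <- qi != si
    qi <- qi[keep]; si <- si[keep]
    if (!length(qi)) next
    dup <- duplicated(paste(qi, si))
    qi <- qi[!dup]; si <- si[!dup]
    ev <- 10^-runif(length(qi), 5, 60)
    h <- mk_ht(data.frame(query_id = ids[qi], subject_id = ids[si],
                          evalue = ev, bitscore = -log10(ev) * 2,
                          stringsAsFactors = FALSE))
    res <- merge_seeds(cands, h, caps, ids)
    # oracle: explicit adjacency + boolean closure
    adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    for (k in seq_along(qi)) {
      if (ev[k] < caps[[ids[qi[k]]]]$evalue)
        adj[qi[k], si[k]] <- TRUE
    }
    oracle <- unname(oracle_closure_clusters(adj))
    mine <- match(res$merge_map[ids], ids)
    # identical partitions: identical co-membership matrices
    expect_identical(outer(mine, mine, `==`), outer(oracle, oracle, `==`))
  }
})

test_that("HPPG growth admits below the cap and trims to the first methionine", {
  seqs <- make_records(c("pennates|p|f", "corethron|c|f", "px_clade|x|f"),
                       c("MSEED", "GAVMKL", "MOK"),
                       subcats = c("pennates", "corethron", "px_clade"))
  seqs$residues[3L] <- "MAAA"
  cap <- structure(list(seed_id = "pennates|p|f", evalue = 1e-30,
                        bitscore = 100, rank = 3L, open = FALSE),
                   class = "outgroup_cap")
  h <- mk_ht(data.frame(
    query_id = "pennates|p|f",
    subject_id = c("corethron|c|f", "px_clade|x|f"),
    evalue = c(1e-40, 1e-30), bitscore = c(150, 100),
    stringsAsFactors = FALSE))
  hp <- grow_hppg("pennates|p|f", h, cap, seqs)
  expect_true("corethron|c|f" %in% hp$member_ids)   # 1e-40 < cap
  expect_false("px_clade|x|f" %in% hp$member_ids)   # equality rejected
  expect_equal(hp$members$residues[hp$members$seq_id == "corethron|c|f"],
               "MKL") # GAVMKL trimmed at the first methionine
  expect_equal(sum(hp$presence), 2L)
})

test_that("members without methionine are excluded with a message", {
  seqs <- make_records(c("pennates|p|f", "corethron|c|f"),
                       c("MSEED", "GAVKL"),
                       subcats = c("pennates", "corethron"))
  cap <- structure(list(seed_id = "pennates|p|f", evalue = 1e-10,
                        bitscore = 10, rank = 1L, open = FALSE),
                   class = "outgroup_cap")
  h <- mk_ht(data.frame(query_id = "pennates|p|f",
                        subject_id = "corethron|c|f",
                        evalue = 1e-40, bitscore = 150,
                        stringsAsFactors = FALSE))
  expect_message(hp <- grow_hppg("pennates|p|f", h, cap, seqs),
                 "without methionine")
  expect_equal(hp$member_ids, "pennates|p|f")
})

test_that("conservation patterns follow the published inclusive majorities", {
  tax <- default_taxonomy()
  pres <- function(subs) hppg_presence(subs, tax)
  # 2/3 chrysista + 3/5 diatoms, no hypogyristea -> P1 only
  p1 <- evaluate_conservation(pres(c("px_clade", "raphidophytes",
                                     "corethron", "radial_centrics",
                                     "pennates")))
  expect_equal(p1, "P1")
  # 1/3 chrysista + 2/3 hypogyristea + 3/5 diatoms -> P3 only
  p3 <- evaluate_conservation(pres(c("px_clade", "pelagophytes",
                                     "dictyochophytes", "corethron",
                                     "radial_centrics", "pennates")))
  expect_equal(p3, "P3")
  # empty presence: nothing passes, status stays candidate
  hp <- structure(list(hppg_id = "x", seed_id = "x", member_ids = "x",
                       members = make_records("x", "M"),
                       presence = pres(character(0)),
                       patterns_passed = character(0),
                       status = "candidate"), class = "hppg")
  hp <- evaluate_conservation(hp)
  expect_equal(hp$patterns_passed, character(0))
  expect_equal(hp$status, "candidate")
})

test_that("adding members never removes a passed pattern (monotonicity)", {
  tax <- default_taxonomy()
  och <- unlist(tax$ochrophyte_groups, use.names = FALSE)
  set.seed(5)
  for (i in 1:50) {
    subs <- sample(och, sample(3:9, 1L), replace = TRUE)
    before <- evaluate_conservation(hppg_presence(subs, tax))
    after <- evaluate_conservation(
      hppg_presence(c(subs, sample(och, 1L)), tax))
    expect_true(all(before %in% after))
  }
})

test_that("pattern selection ranks by control separation chi-squared", {
  tax <- default_taxonomy()
  full <- hppg_presence(unlist(tax$ochrophyte_groups), tax)
  empty <- hppg_presence(character(0), tax)
  pos <- rep(list(full), 20)
  neg <- rep(list(empty), 20)
  pats <- conservation_patterns()
  rank <- select_conservation_patterns(pats, pos, neg, tax)
  # perfect separation: every pattern separates fully, statistic equal
  expect_true(all(rank$pos_pass == 20L))
  expect_true(all(rank$neg_pass == 0L))
  # hand-computed 2x2 chi-squared for a mixed table: 15/20 vs 5/20 pass
  chry <- hppg_presence(c("px_clade", "raphidophytes", "corethron",
                          "radial_centrics", "pennates"), tax) # passes P1
  pos2 <- c(rep(list(chry), 15), rep(list(empty), 5))
  neg2 <- c(rep(list(chry), 5), rep(list(empty), 15))
  rank2 <- select_conservation_patterns(pats, pos2, neg2, tax)
  tab <- rbind(c(15, 5), c(5, 15))
  hand <- sum((tab - outer(rowSums(tab), colSums(tab)) / sum(tab))^2 /
                (outer(rowSums(tab), colSums(tab)) / sum(tab)))
  expect_equal(rank2$statistic[rank2$pattern == "P1"], hand,
               tolerance = 1e-12)
  # identical pass rates in both sets: statistic 0
  rank3 <- select_conservation_patterns(
    pats, rep(list(chry), 10), rep(list(chry), 10), tax)
  expect_true(all(rank3$statistic == 0))
})

test_that("alignment curation removes late starters and early terminators", {
  tax <- default_taxonomy()
  set.seed(21)
  ncol_ <- 200L
  subs <- c("px_clade", "raphidophytes", "pelagophytes", "dictyochophytes",
            "corethron", "radial_centrics", "pennates")
  ids <- paste0(subs, "|sp|f")
  base <- sample(c("A", "L", "K"), ncol_, replace = TRUE)
  aln <- matrix(rep(base, length(ids)), nrow = length(ids), byrow = TRUE)
  rownames(aln) <- ids
  late <- aln[1L, ]; late[1:60] <- "-"      # starts 60 positions late
  ok10 <- aln[2L, ]; ok10[1:10] <- "-"      # starts 10 positions late
  aln["px_clade|sp|f", ] <- late
  aln["raphidophytes|sp|f", ] <- ok10
  seqs <- make_records(ids, apply(aln, 1L, function(r)
    paste(r[r != "-"], collapse = "")), subcats = subs)
  hp <- structure(list(hppg_id = ids[3L], seed_id = ids[3L],
                       member_ids = ids, members = seqs,
                       presence = hppg_presence(subs, tax),
                       patterns_passed = character(0),
                       status = "conserved"), class = "hppg")
  cur <- curate_alignment(hp, aln)
  expect_true("px_clade|sp|f" %in% cur$removed)
  expect_false("raphidophytes|sp|f" %in% cur$removed)
  # early termination: last residue before the conserved-domain end
  short <- aln
  cut <- short["raphidophytes|sp|f", ]
  cut[100:ncol_] <- "-"
  short["raphidophytes|sp|f", ] <- cut
  hp2 <- hp
  cur2 <- curate_alignment(hp2, short)
  expect_true("raphidophytes|sp|f" %in% cur2$removed)
  # removal that drops conservation below every pattern eliminates the HPPG
  few <- c("px_clade", "raphidophytes", "pelagophytes", "dictyochophytes")
  ids3 <- paste0(few, "|sp|f")
  aln3 <- matrix(rep(base, 4), nrow = 4, byrow = TRUE,
                 dimnames = list(ids3, NULL))
  aln3[1L, 1:70] <- "-"
  hp3 <- structure(list(hppg_id = ids3[2L], seed_id = ids3[2L],
                        member_ids = ids3,
                        members = make_records(ids3, rep("M", 4),
                                               subcats = few),
                        presence = hppg_presence(few, tax),
                        patterns_passed = character(0),
                        status = "conserved"), class = "hppg")
  cur3 <- curate_alignment(hp3, aln3)
  expect_null(cur3$hppg)
})

test_that("column trimming keeps columns at the boundary fraction", {
  aln <- matrix("A", nrow = 10, ncol = 3,
                dimnames = list(paste0("s", 1:10), NULL))
  aln[1:4, 1L] <- "-"  # 6/10 residues: kept
  aln[1:6, 2L] <- "-"  # 4/10: removed
  aln[1:5, 3L] <- "-"  # exactly 5/10: kept (inclusive)
  out <- trim_columns(aln, 0.5)
  expect_equal(attr(out, "kept_columns"), c(1L, 3L))
  expect_error(trim_columns(matrix("-", 2, 2,
                                   dimnames = list(c("a", "b"), NULL))),
               "vanished")
})

test_that("the ochrophyte clade check allows one interrupting group only", {
  tax <- default_taxonomy()
  och7 <- "((px_clade,raphidophytes),(pelagophytes,(corethron,(radial_centrics,(polar_centrics,pennates)))))"
  pure <- ape::read.tree(text = paste0("(", och7,
                                       ",(cyanidiales,florideophytes));"))
  expect_true(check_ochrophyte_clade(annotate_tree(pure, tax))$pass)
  # interrupted by red algae only: still passes
  one <- ape::read.tree(text = paste0(
    "(((px_clade,raphidophytes),(cyanidiales,(pelagophytes,(corethron,",
    "(radial_centrics,(polar_centrics,pennates)))))),",
    "(oomycetes,labyrinthulomycetes));"))
  expect_true(check_ochrophyte_clade(annotate_tree(one, tax))$pass)
  # interrupted by red AND green: fails
  two <- ape::read.tree(text = paste0(
    "(((px_clade,raphidophytes),(cyanidiales,(core_chlorophytes,",
    "(pelagophytes,(corethron,(radial_centrics,(polar_centrics,",
    "pennates))))))),(oomycetes,labyrinthulomycetes));"))
  expect_false(check_ochrophyte_clade(annotate_tree(two, tax))$pass)
  # tiny trees are uninformative
  tiny <- ape::read.tree(text = "((pennates,corethron),cyanidiales);")
  res <- check_ochrophyte_clade(annotate_tree(tiny, tax))
  expect_false(res$pass)
  expect_equal(res$reason, "uninformative")
})
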