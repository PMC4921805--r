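tree4 <- read_newick_tree(text = "((A,B)ab,(C,D)cd)root;")

test_that("polarization on a known quartet recovers direction and branch", {
  # one clade-defining mutation
  vt <- make_vt(
    matrix(c("T", "T", "G", "G"), 1,
      dimnames = list(NULL, c("A", "B", "C", "D"))
    ),
    pos = 5L
  )
  a <- polarize_and_assign(vt, tree4, outgroup = "C")
  expect_equal(a$ancestral_allele, "G")
  expect_equal(a$derived_allele, "T")
  expect_equal(a$n_events, 1L)
  expect_equal(a$events[[1]]$branch, "ab")
  expect_equal(a$events[[1]]$direction, "forward")
  expect_false(a$homoplasic)
  # matches the exhaustive-enumeration minimum
  expect_equal(
    a$n_events,
    oracle_parsimony(tree4, c(A = "T", B = "T", C = "G", D = "G"), c("G", "T"))
  )

  # a recurrent mutation: two independent forward events
  vt2 <- make_vt(
    matrix(c("T", "G", "T", "G"), 1,
      dimnames = list(NULL, c("A", "B", "C", "D"))
    ),
    pos = 9L
  )
  a2 <- polarize_and_assign(vt2, tree4, outgroup = "D")
  expect_equal(a2$ancestral_allele, "G")
  expect_equal(a2$n_events, 2L)
  expect_true(a2$homoplasic)
  expect_setequal(a2$events[[1]]$branch, c("A", "C"))
  expect_equal(a2$events[[1]]$direction, c("forward", "forward"))
  expect_equal(
    a2$n_events,
    oracle_parsimony(tree4, c(A = "T", B = "G", C = "T", D = "G"), c("G", "T"))
  )
})

test_that("back mutations are oriented relative to the ancestral allele", {
  tr <- read_newick_tree(text = "(((A,B)ab,C)abc,D)root;")
  vt <- make_vt(
    matrix(c("T", "G", "T", "G"), 1,
      dimnames = list(NULL, c("A", "B", "C", "D"))
    )
  )
  a <- polarize_and_assign(vt, tr, outgroup = "D")
  expect_equal(a$ancestral_allele, "G")
  expect_equal(a$n_events, 2L)
  ev <- a$events[[1]]
  expect_equal(ev$direction[ev$branch == "abc"], "forward")
  expect_equal(ev$direction[ev$branch == "B"], "back")
  # V370-like structure: k back mutations give n_events = k + 1 and
  # recurrent_events = k
  s <- count_events(a)
  expect_equal(s$total_events, s$n_variants + s$recurrent_events)
})

test_that("event counts equal the exhaustive parsimony minimum on random cases", {
  set.seed(1203)
  for (rep in 1:40) {
    ntip <- sample(4:8, 1)
    tr <- random_tree(ntip)
    g <- sample(c("A", "G"), ntip, replace = TRUE)
    # sprinkle missing data in a quarter of the cases
    if (rep %% 4 == 0) g[sample(ntip, 1)] <- "N"
    names(g) <- tr$tip.label
    if (length(unique(g[g != "N"])) < 2) next
    vt <- make_vt(matrix(g, 1, dimnames = list(NULL, names(g))))
    a <- suppressWarnings(polarize_and_assign(vt, tr))
    expect_equal(
      a$n_events, oracle_parsimony(tr, g, c("A", "G")),
      info = paste("rep", rep)
    )
  }
})

test_that("event counts agree with phangorn's Fitch parsimony score", {
  set.seed(77)
  for (rep in 1:10) {
    ntip <- sample(5:10, 1)
    tr <- random_tree(ntip)
    g <- sample(c("A", "G"), ntip, replace = TRUE)
    names(g) <- tr$tip.label
    if (length(unique(g)) < 2) next
    vt <- make_vt(matrix(g, 1, dimnames = list(NULL, names(g))))
    a <- polarize_and_assign(vt, tr)
    dat <- phangorn::phyDat(
      matrix(g, ncol = 1, dimnames = list(names(g), NULL)),
      type = "DNA"
    )
    expect_equal(a$n_events, as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("polarity is stable under tip reordering and tree relabeling", {
  set.seed(42)
  tr <- random_tree(8)
  g <- setNames(sample(c("A", "G", "N"), 8, replace = TRUE, prob = c(.45, .45, .1)),
                tr$tip.label)
  g[1:2] <- c("A", "G") # keep it segregating
  vt <- make_vt(matrix(g, 1, dimnames = list(NULL, names(g))))
  a <- polarize_and_assign(vt, tr)
  perm <- sample(length(g))
  vt_p <- make_vt(matrix(g[perm], 1, dimnames = list(NULL, names(g)[perm])))
  a_p <- polarize_and_assign(vt_p, tr)
  expect_equal(a_p$n_events, a$n_events)
  expect_equal(a_p$ancestral_allele, a$ancestral_allele)
  expect_setequal(a_p$events[[1]]$branch, a$events[[1]]$branch)
})

test_that("variants map to the branch where they were simulated when homoplasy-free", {
  sim <- simulate_dataset(
    sim_config(seed = 31, mut_rate = 0.4, conv_rate = 0, locus_length = 2000)
  )
  mut <- sim$truth[sim$truth$kind == "mutation", ]
  # keep sites hit exactly once (homoplasy-free subset)
  once <- mut[!(mut$start %in% mut$start[duplicated(mut$start)]), ]
  a <- suppressWarnings(
    polarize_and_assign(sim$variants, sim$tree, on_multiallelic = "drop")
  )
  hit <- a[a$pos %in% once$start & a$n_events == 1L, ]
  expect_gt(nrow(hit), 0L)
  for (i in seq_len(nrow(hit))) {
    expect_equal(
      hit$events[[i]]$branch,
      once$branch[match(hit$pos[i], once$start)]
    )
  }
})

test_that("degenerate variants and unknown samples are handled explicitly", {
  vt <- make_vt(
    matrix(c("T", "T", "G", "G"), 1, dimnames = list(NULL, c("A", "B", "C", "E"))),
    pos = 1L
  )
  expect_error(polarize_and_assign(vt, tree4), "sample not on tree: E")

  g <- matrix(c("N", "N", "N", "G"), 1, dimnames = list(NULL, c("A", "B", "C", "D")))
  df <- data.frame(
    name = "V1", chrom = "chrY", pos = 1L, type = "SNP", indel_length = 0L,
    ref_allele = "G", alt_allele = "T", flag_missing = TRUE,
    multiallelic = FALSE, A = "N", B = "N", C = "N", D = "N",
    stringsAsFactors = FALSE
  )
  vt_allN <- variant_table(df, c("A", "B", "C", "D"))
  expect_warning(out <- polarize_and_assign(vt_allN, tree4), "all-missing")
  expect_equal(nrow(out), 0L)

  df$A <- df$B <- df$C <- df$D <- "G"
  vt_mono <- variant_table(df, c("A", "B", "C", "D"))
  expect_warning(polarize_and_assign(vt_mono, tree4), "non-segregating")

  df$A <- "T"; df$B <- "C"; df$C <- "G"; df$D <- "G"
  df$multiallelic <- TRUE
  vt_multi <- variant_table(df, c("A", "B", "C", "D"))
  expect_error(polarize_and_assign(vt_multi, tree4), "multi-allelic")
  expect_warning(
    out2 <- polarize_and_assign(vt_multi, tree4, on_multiallelic = "drop"),
    "skipped"
  )
  expect_equal(nrow(out2), 0L)
})

test_that("event accounting satisfies the sum rule on simulated panels", {
  for (s in c(2, 3)) {
    sim <- simulate_dataset(sim_config(seed = s))
    a <- suppressWarnings(
      polarize_and_assign(sim$variants, sim$tree, on_multiallelic = "drop")
    )
    cnt <- count_events(a)
    expect_equal(cnt$total_events, cnt$n_variants + cnt$recurrent_events)
    expect_equal(cnt$total_events, sum(a$n_events))
    expect_equal(cnt$n_homoplasic, sum(a$n_events > 1))
  }
})

test_that("homoplasy-rate comparison behaves as a two-sided Fisher test", {
  expect_equal(compare_homoplasy_rates(0, 10, 0, 10), 1)
  # enumeration over the three tables with margins (2,2)/(2,2)
  expect_equal(compare_homoplasy_rates(2, 2, 0, 2), 1 / 3)
  expect_lt(compare_homoplasy_rates(14, 51, 4, 2386), 1e-4)
  expect_error(compare_homoplasy_rates(5, 4, 0, 2))
})
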