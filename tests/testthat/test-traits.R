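mk_matrix <- function(m) character_matrix(m)

test_that("majority, pair combination and derived counts follow their rules", {
  expect_identical(unname(majority_state(rbind(c("1"), c("1"), c("0")))), "1")
  expect_identical(unname(majority_state(rbind(c("1"), c("0")))), "?")
  expect_identical(unname(majority_state(rbind(c("?"), c("?")))), "?")
  # 17 synthetic rows with known majorities
  set.seed(90)
  truth <- sample(c("0", "1"), 20, TRUE)
  rows <- t(replicate(17, truth))
  flip <- matrix(runif(17 * 20) < 0.2, 17)   # minority flips
  rows[flip] <- ifelse(rows[flip] == "0", "1", "0")
  # force clear majorities: at most 6 of 17 flipped per character
  for (j in which(colSums(flip) > 6)) rows[flip[, j], j] <- truth[j]
  expect_identical(unname(majority_state(rows)), truth)

  expect_identical(unname(combine_pair("1", "1")), "1")
  expect_identical(unname(combine_pair("1", "?")), "1")
  expect_identical(unname(combine_pair("?", "0")), "0")
  expect_identical(unname(combine_pair("1", "0")), "?")

  dmap <- setNames(rep("1", 20), paste0("c", 1:20))
  all_der <- setNames(rep("1", 20), paste0("c", 1:20))
  expect_identical(count_derived(all_der, dmap)$label, "20/20")
  expect_identical(count_derived(setNames(rep("?", 20), paste0("c", 1:20)),
                                 dmap)$label, "0/20")
  mixed <- all_der; mixed[1:5] <- "0"
  expect_identical(count_derived(mixed, dmap)$label, "15/20")
})

test_that("character distances equal a brute-force double loop", {
  a <- c(rep("1", 5), rep("0", 15))
  b <- c(rep("0", 5), rep("0", 15))
  m <- mk_matrix(rbind(t1 = a, t2 = b, t3 = a))
  D <- character_distance(m)
  expect_equal(D["t1", "t2"], 0.25)
  expect_equal(D["t1", "t3"], 0)
  set.seed(91)
  r <- matrix(sample(c("0", "1", "?"), 5 * 12, TRUE, prob = c(.4, .4, .2)), 5,
              dimnames = list(paste0("x", 1:5), paste0("c", 1:12)))
  Dm <- suppressWarnings(character_distance(mk_matrix(r)))
  for (i in 1:4) for (j in (i + 1):5) {
    comp <- 0; mis <- 0
    for (k in 1:12) {
      if (r[i, k] != "?" && r[j, k] != "?") {
        comp <- comp + 1
        if (r[i, k] != r[j, k]) mis <- mis + 1
      }
    }
    expect_equal(Dm[i, j], if (comp) mis / comp else 0)
  }
})

test_that("NJ is exact on additive distances and matches closed forms", {
  tr <- ape::read.tree(text = "((a:2,b:3):1,(c:1.5,(d:2,e:1):0.5):1.2,f:4);")
  D <- ape::cophenetic.phylo(tr)
  nj1 <- neighbor_joining(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj1), 0, ignore_attr = TRUE)
  expect_equal(sort(nj1$edge.length), sort(ape::unroot(tr)$edge.length),
               tolerance = 1e-9)
  # 3 taxa: unique topology, closed-form branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- neighbor_joining(D3)
  expect_equal(sort(t3$edge.length), sort(c((3 + 4 - 5) / 2, (3 + 5 - 4) / 2,
                                            (4 + 5 - 3) / 2)), tolerance = 1e-9)
  # ultrametric 4-taxon matrix recovers the generating split
  D4 <- matrix(c(0, 2, 6, 6,  2, 0, 6, 6,  6, 6, 0, 2,  6, 6, 2, 0), 4,
               dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  t4 <- neighbor_joining(D4)
  gen <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);")
  expect_equal(ape::dist.topo(ape::unroot(gen), t4), 0, ignore_attr = TRUE)
  expect_error(neighbor_joining(matrix(c(0, 1, 1, 0), 2)), "3 taxa")
  Dbad <- D3; Dbad[1, 2] <- 99
  expect_error(neighbor_joining(Dbad), "symmetric")
})

test_that("NJ agrees with the reference implementation on random matrices", {
  skip_if_not_installed("phangorn")
  set.seed(92)
  for (rep in 1:5) {
    n <- 7
    D <- as.matrix(dist(matrix(runif(n * 4), n)))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- neighbor_joining(D)
    ref <- ape::nj(D)
    expect_equal(ape::dist.topo(mine, ref), 0, ignore_attr = TRUE)
  }
})

test_that("Fitch scores match the textbook case and exhaustive enumeration", {
  taxa <- c("a", "b", "c", "d")
  m <- mk_matrix(matrix(c("0", "0", "1", "1"), 4, 1,
                        dimnames = list(taxa, "c1")))
  match_tree <- ape::read.tree(text = "((a,b),(c,d));")
  other_tree <- ape::read.tree(text = "((a,c),(b,d));")
  expect_identical(fitch_score(match_tree, m), 1L)
  expect_identical(fitch_score(other_tree, m), 2L)
  cm0 <- mk_matrix(matrix("1", 4, 3, dimnames = list(taxa, paste0("c", 1:3))))
  expect_identical(fitch_score(match_tree, cm0), 0L)

  # brute-force oracle: jointly enumerate every state assignment to internal
  # nodes and to ambiguous ('?') tips, count changes over edges, take the min
  brute_fitch <- function(tree, states) {
    tree <- ape::unroot(tree)
    ntip <- length(tree$tip.label)
    internals <- sort(unique(tree$edge[tree$edge > ntip]))
    total <- 0
    for (ch in seq_len(ncol(states))) {
      syms <- unique(states[, ch][states[, ch] != "?"])
      if (!length(syms)) next
      tip_states <- states[tree$tip.label, ch]
      free <- c(internals, which(tip_states == "?"))
      grid <- expand.grid(rep(list(syms), length(free)),
                          stringsAsFactors = FALSE)
      best <- Inf
      for (g in seq_len(nrow(grid))) {
        value <- function(v) {
          k <- match(v, free)
          if (!is.na(k)) as.character(grid[g, k]) else tip_states[v]
        }
        changes <- sum(vapply(seq_len(nrow(tree$edge)), function(e)
          value(tree$edge[e, 1]) != value(tree$edge[e, 2]), logical(1)))
        best <- min(best, changes)
      }
      total <- total + best
    }
    total
  }
  set.seed(93)
  for (rep in 1:3) {
    st <- matrix(sample(c("0", "1", "?"), 60, TRUE, prob = c(.45, .45, .1)), 6,
                 dimnames = list(paste0("t", 1:6), paste0("c", 1:10)))
    cm <- mk_matrix(st)
    tr <- ape::unroot(ape::rtree(6, tip.label = paste0("t", 1:6)))
    expect_identical(fitch_score(tr, cm), as.integer(brute_fitch(tr, st)))
  }
})

test_that("Fitch score is invariant to rooting and leaf permutation", {
  skip_if_not_installed("phangorn")
  set.seed(94)
  st <- matrix(sample(c("0", "1"), 70, TRUE), 7,
               dimnames = list(paste0("t", 1:7), paste0("c", 1:10)))
  cm <- mk_matrix(st)
  tr <- ape::unroot(ape::rtree(7, tip.label = paste0("t", 1:7)))
  base <- fitch_score(tr, cm)
  expect_identical(base, fitch_score(ape::root(tr, "t3", resolve.root = TRUE), cm))
  rot <- ape::rotateConstr(tr, sample(tr$tip.label))
  expect_identical(base, fitch_score(rot, cm))
  pd <- phangorn::phyDat(st, type = "USER", levels = c("0", "1"))
  expect_equal(base, phangorn::fitch(tr, pd), ignore_attr = TRUE)
})

test_that("exhaustive MP recovers compatible matrices and stars conflicts", {
  # homoplasy-free characters generated from a known tree: unique MP tree
  gen <- ape::read.tree(text = "((a,b),(c,(d,e)),f);")
  splits <- list(c("a", "b"), c("d", "e"), c("d", "e", "c"))
  taxa <- sort(gen$tip.label)
  st <- vapply(splits, function(s) ifelse(taxa %in% s, "1", "0"),
               character(6))
  st <- cbind(st, st)   # two copies of each character
  dimnames(st) <- list(taxa, paste0("c", seq_len(ncol(st))))
  mp <- exhaustive_mp(mk_matrix(st))
  expect_identical(mp$n_topologies, 105L)
  expect_identical(mp$score, as.integer(length(splits) * 2))
  expect_length(mp$trees, 1L)
  expect_equal(ape::dist.topo(mp$trees[[1]], ape::unroot(gen)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::dist.topo(mp$strict_consensus, ape::unroot(gen)), 0,
               ignore_attr = TRUE)
  # two conflicting characters on 4 taxa: >= 2 MP trees, star consensus
  st4 <- matrix(c("0", "0", "1", "1",
                  "0", "1", "0", "1"), 4, 2,
                dimnames = list(c("a", "b", "c", "d"), c("c1", "c2")))
  mp4 <- exhaustive_mp(mk_matrix(st4))
  expect_gte(length(mp4$trees), 2L)
  expect_identical(mp4$strict_consensus$Nnode, 1L)   # star
  expect_error(exhaustive_mp(mk_matrix(st4), max_taxa = 3), "out of scope")
})

test_that("exhaustive MP minimum matches the reference search", {
  skip_if_not_installed("phangorn")
  set.seed(95)
  st <- matrix(sample(c("0", "1"), 60, TRUE), 6,
               dimnames = list(paste0("t", 1:6), paste0("c", 1:10)))
  mp <- exhaustive_mp(mk_matrix(st))
  pd <- phangorn::phyDat(st, type = "USER", levels = c("0", "1"))
  ref_scores <- vapply(phangorn::allTrees(6, tip.label = paste0("t", 1:6)),
                       function(t) phangorn::fitch(t, pd), numeric(1))
  expect_equal(mp$score, min(ref_scores), ignore_attr = TRUE)
  expect_identical(length(mp$trees), sum(ref_scores == min(ref_scores)))
})

test_that("strict consensus keeps exactly the universally shared splits", {
  trees <- list(ape::read.tree(text = "((a,b),(c,d),(e,f));"),
                ape::read.tree(text = "((a,b),((c,d),e),f);"),
                ape::read.tree(text = "(((a,b),c),(d,e),f);"))
  cons <- strict_consensus(trees)
  sp <- virtucrania:::tree_splits(cons, sort(trees[[1]]$tip.label))
  shared <- Reduce(intersect, lapply(trees, virtucrania:::tree_splits,
                                     taxa = sort(trees[[1]]$tip.label)))
  expect_setequal(sp, shared)
  # cross-check against the reference consensus
  ref <- ape::consensus(trees, p = 1)
  expect_equal(ape::dist.topo(ape::unroot(cons), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("NEXUS and Newick round trips preserve the data", {
  set.seed(96)
  st <- matrix(sample(c("0", "1", "?"), 40, TRUE), 5,
               dimnames = list(paste0("tax", 1:5), paste0("char", 1:8)))
  cm <- mk_matrix(st)
  path <- file.path(tempdir(), "traits.nex")
  write_nexus_matrix(cm, path)
  back <- read_nexus_matrix(path)   # NEXUS carries no character names
  expect_identical(back$states, cm$states)
  tr <- ape::rtree(5)
  np <- file.path(tempdir(), "tree.nwk")
  write_newick(tr, np)
  back_tr <- ape::read.tree(np)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back_tr)), 0,
               ignore_attr = TRUE)
})
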