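# helper: wrap a hand-built adjacency array [receiver, sender, time] as a
# binary_dynamic_network
fake_net <- function(adj, labels = paste0("ch", seq_len(dim(adj)[1])),
                     fs = 32, t0 = dim(adj)[3] %/% 2) {
  dimnames(adj) <- list(labels, labels, NULL)
  structure(list(adj = adj, alpha = 0.01, bonferroni = FALSE,
                 n_nodes = dim(adj)[1], channel_labels = labels,
                 fs = fs, t0_index = t0, first_valid = 1L),
            class = "binary_dynamic_network")
}

test_that("out-degree counts outgoing edges and conserves the edge total", {
  n <- 16; nt <- 20
  full <- array(1, dim = c(n, n, nt))
  for (t in 1:nt) diag(full[, , t]) <- 0
  k <- out_degree_matrix(fake_net(full))
  expect_true(all(k$k == n - 1))

  empty <- array(0, dim = c(4, 4, 5))
  expect_true(all(out_degree_matrix(fake_net(empty))$k == 0))

  a <- array(0, dim = c(6, 6, 10))
  a[c(1, 3, 5), 2, 7] <- 1          # node 2 sends to 1, 3, 5 at t = 7
  k2 <- out_degree_matrix(fake_net(a))
  expect_equal(unname(k2$k[2, 7]), 3)
  # conservation: column sums of k over nodes = total edge count per time
  set.seed(28)
  r <- array(rbinom(6 * 6 * 10, 1, 0.3), dim = c(6, 6, 10))
  for (t in 1:10) diag(r[, , t]) <- 0
  kr <- out_degree_matrix(fake_net(r))
  expect_equal(colSums(kr$k), apply(r, 3, sum))
})

test_that("binarization respects the threshold comparison and monotonicity", {
  a <- array(0, dim = c(5, 5, 3))
  a[2:4, 1, 2] <- 1                  # node 1 out-degree exactly 3 at t = 2
  k <- out_degree_matrix(fake_net(a))
  expect_equal(unname(binarize_out_degree(k, 3, "greater")$b[1, 2]), 0)
  expect_equal(unname(binarize_out_degree(k, 3, "greater_equal")$b[1, 2]), 1)
  a[2:5, 1, 3] <- 1                  # out-degree 4
  k <- out_degree_matrix(fake_net(a))
  expect_equal(unname(binarize_out_degree(k, 3)$b[1, 3]), 1)
  expect_true(all(binarize_out_degree(out_degree_matrix(fake_net(
    array(0, dim = c(4, 4, 3)))))$b == 0))
  # raising the threshold never turns a 0 into a 1
  set.seed(29)
  r <- array(rbinom(8 * 8 * 6, 1, 0.5), dim = c(8, 8, 6))
  kr <- out_degree_matrix(fake_net(r))
  for (th in 0:6)
    expect_true(all(binarize_out_degree(kr, th + 1)$b <=
                    binarize_out_degree(kr, th)$b))
})

test_that("background detection keys on baseline-window activity", {
  n <- 6; nt <- 64
  adj <- array(0, dim = c(n, n, nt))
  adj[2:6, 1, ] <- 1                 # node 1 strong throughout
  adj[c(2, 3, 4, 6), 5, 40:64] <- 1  # node 5 active only later
  b <- binarize_out_degree(out_degree_matrix(fake_net(adj, t0 = 32)))
  bg <- identify_background(b, baseline_window = c(1, 16))
  expect_true("ch1" %in% bg)
  expect_false("ch5" %in% bg)
  none <- binarize_out_degree(out_degree_matrix(fake_net(
    array(0, dim = c(n, n, nt)), t0 = 32)))
  expect_length(identify_background(none, c(1, 16)), 0)
  expect_error(identify_background(b, c(40, 60)), "precede")
})

test_that("localization finds the earliest sustained non-background channel", {
  labels <- standard_1020_labels()
  n <- 16; nt <- 96
  adj <- array(0, dim = c(n, n, nt))
  o1 <- match("O1", labels); f7 <- match("F7", labels)
  adj[setdiff(1:n, o1), o1, ] <- 1          # O1 background throughout
  adj[c(1, 3, 5, 7, 13), f7, 40:70] <- 1    # F7 activates at index 40
  b <- binarize_out_degree(out_degree_matrix(fake_net(adj, labels, t0 = 48)))
  bg <- identify_background(b, c(1, 32))
  expect_identical(as.character(bg), "O1")
  loc <- locate_ez(b, bg)
  expect_identical(loc$electrode, "F7")
  expect_equal(loc$onset_index, 40)
  expect_false("O1" %in% loc$electrode)
})

test_that("onset ties break toward the longer activation", {
  n <- 6; nt <- 60
  adj <- array(0, dim = c(n, n, nt))
  adj[2:5, 1, 30:31] <- 1            # ch1: 2-point activation at 30
  adj[c(1, 3, 4, 5), 2, 30:39] <- 1  # ch2: 10-point activation at 30
  b <- binarize_out_degree(out_degree_matrix(fake_net(adj, t0 = 45)))
  loc <- locate_ez(b, character(0), baseline_window = c(1, 10))
  expect_identical(loc$electrode, "ch2")
  expect_setequal(loc$ties, c("ch1", "ch2"))
})

test_that("no activation gives an explicit not-localizable result", {
  adj <- array(0, dim = c(4, 4, 40))
  b <- binarize_out_degree(out_degree_matrix(fake_net(adj, t0 = 20)))
  loc <- locate_ez(b, character(0), baseline_window = c(1, 10))
  expect_false(loc$localizable)
  expect_true(is.na(loc$electrode))
})

test_that("localization is invariant to channel relabeling", {
  set.seed(30)
  n <- 8; nt <- 80
  adj <- array(rbinom(n * n * nt, 1, 0.02), dim = c(n, n, nt))
  adj[c(1, 2, 4, 6, 7), 3, 50:60] <- 1
  labels <- paste0("ch", 1:n)
  b1 <- binarize_out_degree(out_degree_matrix(fake_net(adj, labels, t0 = 60)))
  loc1 <- locate_ez(b1, character(0), baseline_window = c(1, 20))
  perm <- sample(n)
  b2 <- binarize_out_degree(out_degree_matrix(
    fake_net(adj[perm, perm, , drop = FALSE], labels[perm], t0 = 60)))
  loc2 <- locate_ez(b2, character(0), baseline_window = c(1, 20))
  expect_identical(loc1$electrode, loc2$electrode)
})

test_that("patient-level aggregation takes the majority and reports ties", {
  mk <- function(el, onset = 0) structure(
    list(electrode = el, onset_index = 10L, onset_time_s = onset,
         localizable = !is.na(el), background = character(0),
         ties = character(0)), class = "ez_localization")
  agg <- aggregate_patient(list(mk("F7"), mk("F7"), mk("T3")))
  expect_identical(agg$electrode, "F7")
  expect_equal(unname(agg$votes["F7"]), 2)
  expect_identical(aggregate_patient(list(mk("T3")))$electrode, "T3")
  tie <- aggregate_patient(list(mk("F7", -1), mk("T3", 0)))
  expect_setequal(tie$ties, c("F7", "T3"))
  expect_identical(tie$electrode, "F7")   # earlier median onset wins
  none <- aggregate_patient(list(mk(NA_character_), mk(NA_character_)))
  expect_false(none$localizable)
})
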