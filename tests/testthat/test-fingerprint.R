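test_that("surface-contact bits follow nearest-probe thresholding", {
  anchors <- rbind(A = c(0, 0), B = c(10, 0), C = c(0, 10))
  lig <- ligand(c(0, 0), c(3, 0))
  bits <- compute_bits(lig, anchors, contact_cutoff = 2)
  expect_identical(unname(bits), c(TRUE, FALSE, FALSE)) # probe at anchor A
  bits_none <- compute_bits(ligand(c(50, 50), c(53, 50)), anchors, 2)
  expect_false(any(bits_none))
  # random frames vs brute-force distance thresholding
  set.seed(15)
  for (i in 1:10) {
    p <- matrix(stats::rnorm(4, sd = 6), 2, 2)
    lig2 <- ligand(p[1, ], p[2, ])
    manual <- apply(anchors, 1, function(a)
      min(sqrt(sum((p[1, ] - a)^2)), sqrt(sum((p[2, ] - a)^2))) < 4.5)
    expect_identical(unname(compute_bits(lig2, anchors)), unname(manual))
  }
  expect_error(compute_bits(lig, anchors, contact_cutoff = 0), "cutoff")
})

test_that("bit tallies are column sums with a shared snapshot count", {
  m <- fingerprint_matrix(
    cbind(A = rep(TRUE, 100), B = rep(FALSE, 100)), "ligA")
  tc <- tally_bits(m)
  expect_equal(unname(tc$Cb["A"]), 100)
  expect_equal(unname(tc$Cb["B"]), 0)
  expect_equal(tc$C0, 100)
  set.seed(8)
  col <- stats::runif(57) > 0.4
  tc2 <- tally_bits(fingerprint_matrix(cbind(X = col), "ligA"))
  manual <- 0L
  for (v in col) if (v) manual <- manual + 1L
  expect_equal(unname(tc2$Cb["X"]), manual)
  expect_error(tally_bits(fingerprint_matrix(matrix(TRUE, 0, 1,
                                                    dimnames = list(NULL, "A")))),
               "empty")
})

test_that("Qb evaluates its closed form and extreme cases", {
  mk <- function(cb, c0) {
    bits <- cbind(R = c(rep(TRUE, cb), rep(FALSE, c0 - cb)))
    tally_bits(fingerprint_matrix(bits))
  }
  # pA = 1, pB = 0: forced maximum
  t1 <- qb_score(mk(100, 100), mk(0, 100))
  expect_equal(t1$Qb, 1)
  expect_equal(t1$Pb, 1)
  # symmetric occupancy: Qb = 0
  t2 <- qb_score(mk(50, 100), mk(50, 100))
  expect_equal(t2$Qb, 0)
  expect_equal(t2$Pb, 0.5)
  # worked value: Cb_A = 60, Cb_B = 20, C0 = 100 -> Pb = 0.75, Qb = 0.3
  t3 <- qb_score(mk(60, 100), mk(20, 100))
  expect_equal(t3$Pb, 0.75)
  expect_equal(t3$Qb, 0.3)
  # mismatched residue sets are rejected
  a <- tally_bits(fingerprint_matrix(cbind(A = TRUE)))
  b <- tally_bits(fingerprint_matrix(cbind(B = TRUE)))
  expect_error(qb_score(a, b), "differ")
})

test_that("Qb bound, zero set and monotonicity hold on the exhaustive grid", {
  c0 <- 100
  cb <- 0:c0
  pa <- matrix(cb / c0, c0 + 1, c0 + 1)
  pb <- t(pa)
  prel <- ifelse(pa + pb == 0, 0.5, pa / (pa + pb))
  qb <- pa * 2 * (prel - 0.5)
  expect_true(all(abs(qb) <= 1))
  expect_equal(max(qb), 1)
  # zero exactly when pA = 0 or pA = pB
  zero <- abs(qb) < 1e-14
  expect_true(all(zero == (pa == 0 | abs(pa - pb) < 1e-14)))
  # with pB fixed, Qb is non-decreasing in pA wherever pA >= pB (below
  # that, the pA-weighting of the signed preference makes Qb dip before
  # rising, so global monotonicity cannot hold)
  for (j in seq_len(c0 + 1)) {
    col <- qb[, j]
    keep <- which(cb / c0 >= (j - 1) / c0)
    expect_true(all(diff(col[keep]) >= -1e-14))
  }
})

test_that("residue ranking sorts by Qb with lexicographic ties", {
  tab <- structure(data.frame(residue = c("M", "X", "Y"),
                              type = "surface_contact",
                              Pb = c(0.9, 0.6, 0.2),
                              Qb = c(0.3, 0.1, -0.2)),
                   class = c("qb_table", "data.frame"))
  expect_equal(rank_residues(tab), c("M", "X", "Y"))
  expect_equal(rank_residues(tab, top_n = 1), "M")
  tie <- tab; tie$Qb <- c(0.3, 0.3, 0.3)
  expect_equal(rank_residues(tie), c("M", "X", "Y"))
  single <- tab[1, ]
  expect_equal(rank_residues(single), "M")
})

test_that("the gatekeeper anchor tops the ranking when only one ligand visits it", {
  # ligand A runs on the WT landscape (Met pocket present), ligand B on a
  # landscape with the Met well removed: the Met anchor must show the
  # largest differential contact
  wt <- build_landscape(landscape_spec())
  nomet <- build_landscape(landscape_spec(genotype = "M124V",
                                          met_scale_m124v = 0))
  anchors <- rbind(Met124 = wt$spec$met_anchor,
                   deep1 = c(2, 0), deep2 = c(-2, 0))
  cfg <- quick_config(n_steps = 60000, save_stride = 200)
  top <- vapply(1:10, function(i) {
    ra <- run_metad(wt, cfg, hill_params(), seed = 400 + i)
    rb <- run_metad(nomet, cfg, hill_params(), seed = 400 + i)
    fa <- compute_fingerprints(ra$trajectory, anchors, 4.5, "A")
    fb <- compute_fingerprints(rb$trajectory, anchors, 4.5, "B")
    rank_residues(qb_score(tally_bits(fa), tally_bits(fb)), 1)
  }, character(1))
  expect_gte(mean(top == "Met124"), 0.8)
})
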