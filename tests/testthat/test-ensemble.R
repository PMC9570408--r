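# build a tiny ensemble by repeating template conformers
ensemble_from_conformers <- function(confs, tpf = 1, replicate = 1L) {
  coords <- array(unlist(lapply(confs, `[[`, "xyz")),
                  dim = c(nrow(confs[[1]]$xyz), 3, length(confs)))
  nad_ensemble(confs[[1]]$topology, coords, tpf, replicate)
}

test_that("replicate concatenation preserves frames, time and boundaries", {
  tpl <- build_template("NADH")
  reps <- lapply(1:3, function(r) {
    ensemble_from_conformers(rep(list(tpl), 4), tpf = 2, replicate = r)
  })
  ens <- concatenate_replicates(reps)
  expect_equal(n_frames(ens), 12)
  expect_equal(frame_times(ens)[4], 4 * 2)
  expect_equal(frame_times(ens)[12], 12 * 2)
  expect_equal(ens$replicate, rep(1:3, each = 4))
  # identity on a single input
  expect_identical(concatenate_replicates(reps[1]), reps[[1]])
  # species mismatch
  other <- ensemble_from_conformers(list(build_template("NAD_plus")))
  expect_error(concatenate_replicates(list(reps[[1]], other)), "mismatch")
})

test_that("replicate histograms average counts with sample SD across replicates", {
  # two identical replicates -> SD identically zero
  v <- c(rep(4.2, 10), rep(9.1, 5))
  h <- replicate_histogram(c(v, v), rep(1:2, each = 15))
  expect_true(all(h$sd == 0))
  expect_equal(sum(h$mean), 15)
  # replicate counts {100, 50} in one bin -> mean 75, sample SD 35.36
  h2 <- replicate_histogram(c(rep(4.25, 100), rep(4.25, 50)),
                            rep(1:2, c(100, 50)), bin_width = 0.5)
  bin <- which(h2$mid == 4.25)
  expect_equal(h2$mean[bin], 75)
  expect_equal(h2$sd[bin], sd(c(100, 50)), tolerance = 1e-12)
  expect_equal(h2$sd[bin], 35.355, tolerance = 1e-3)
  # all frames at 4.25 with width 0.5 occupy exactly the [4.0, 4.5) bin
  occupied <- which(h2$counts[1, ] > 0)
  expect_length(occupied, 1)
  expect_equal(h2$breaks[occupied], 4.0)
  expect_equal(h2$breaks[occupied + 1], 4.5)
  expect_error(replicate_histogram(v, rep(1, 15), bin_width = 0), "positive")
})

test_that("histogram counts conserve the total frame count", {
  set.seed(31)
  vals <- stats::runif(600, 0, 19.9)
  reps <- sample(1:3, 600, replace = TRUE)
  h <- replicate_histogram(vals, reps)
  expect_equal(sum(h$counts), 600)
  for (r in 1:3) expect_equal(sum(h$counts[r, ]), sum(reps == r))
})

fake_metrics <- function(hb1 = 10, hb2 = 10, hb3 = 10, hb4 = 10, d = 13,
                         fold_ev = 10, n = length(hb1)) {
  data.frame(frame = seq_len(max(n, length(hb1))),
             replicate = 1L, d = d,
             hb_o3N_o2A = hb1, hb_o3A_o1N = hb2,
             hb_ribA_o4N = hb3, hb_ribN_o4A = hb4,
             fold_event_distance = fold_ev)
}

test_that("fold tally applies the inclusive 3.3 A cutoff with a per-frame OR rule", {
  # one frame: only the first pair satisfied
  t1 <- track_fold_bins(fake_metrics(hb1 = 3.2))
  expect_equal(unname(t1$counts), c(1, 0, 0, 0))
  expect_equal(t1$most_prevalent, "hb_o3N_o2A")
  # boundary inclusive at 3.3, exclusive above
  expect_equal(unname(track_fold_bins(fake_metrics(hb2 = 3.3))$counts[2]), 1)
  expect_equal(sum(track_fold_bins(fake_metrics())$counts), 0)
  # a two-pair bin counts a frame once even when both member pairs
  # qualify: the bin column carries min(O3'A-O4'N, O2'A-O4'N)
  both <- fake_metrics(hb3 = min(3.0, 3.1))
  expect_equal(unname(track_fold_bins(both)$counts), c(0, 0, 1, 0))
  # tie -> first bin
  tie <- fake_metrics(hb1 = c(3, 10), hb4 = c(10, 3))
  expect_equal(track_fold_bins(tie)$most_prevalent, "hb_o3N_o2A")
})

test_that("two-pair H-bond groups enter metrics as the pair minimum", {
  tpl <- build_template("NADH")
  m <- compute_metrics(tpl)
  xyz <- tpl$xyz
  d2 <- function(a, b) sqrt(sum((xyz[a, ] - xyz[b, ])^2))
  expect_equal(m$hb_ribA_o4N, min(d2("O3'A", "O4'N"), d2("O2'A", "O4'N")))
  expect_equal(m$hb_ribN_o4A, min(d2("O3'N", "O4'A"), d2("O2'N", "O4'A")))
  expect_equal(m$hb_o3A_o1N, d2("O3'A", "O1N"))
})

test_that("folded events use the inclusive 4.0 A O4'N-C4A cutoff", {
  met <- fake_metrics(fold_ev = c(3.9, 4.0, 4.1))
  expect_equal(detect_folded_events(met), c(1L, 2L))
})

test_that("representative frames follow the backward-scan rule", {
  # folded frame at index 100; indices 95-99 carry d = 8.2 9.1 12.0 9.4 6.0
  d <- rep(13, 100)
  d[95:99] <- c(8.2, 9.1, 12.0, 9.4, 6.0)
  d[100] <- 4.0
  met <- data.frame(frame = 1:100, replicate = 1L, d = d)
  tally <- list(most_prevalent = "hb_o3N_o2A",
                frames = list(hb_o3N_o2A = 100L))
  hist <- list(mid = c(4.25, 9.0, 13.25),
               mean = c(1, 10, 60))
  sel <- select_representative_frames(met, tally, hist)
  expect_equal(sel$folded, 100L)
  expect_equal(unname(sel$peaks["semi_extended"]), 9.0)
  expect_equal(sel$semi_extended, 98L)      # d = 9.4, first within 9.0 +- 0.5
  expect_equal(sel$extended, 94L)           # d = 13, first within 13.25 +- 0.5
  # scan never crosses a replicate boundary
  met2 <- met
  met2$replicate <- rep(c(1L, 2L), c(99, 1))
  sel2 <- select_representative_frames(met2, tally, hist)
  expect_length(sel2$semi_extended, 0)
  # no folded frames is a reported condition, not an error
  sel3 <- select_representative_frames(met, list(most_prevalent = "hb_o3N_o2A",
                                                 frames = list(hb_o3N_o2A = integer(0))),
                                       hist)
  expect_length(sel3$folded, 0)
  expect_true(any(grepl("no folded", attr(sel3, "note"))))
})

test_that("RMSD clustering selects greedily with the time-spacing rule", {
  tpl <- build_template("NAD_plus")
  far <- set_dihedral(tpl, "chi_N", 60)   # well above 1 A from reference
  # candidates at 6/12/18 ns (all spaced > 5 ns) -> all three selected
  confs <- rep(list(far), 3)
  confs[c(1, 2, 3)] <- list(tpl, tpl, tpl)
  ens <- ensemble_from_conformers(confs, tpf = 6000)
  expect_equal(cluster_by_rmsd(ens, tpl, spacing_ns = 5), c(1L, 2L, 3L))
  # candidates at 1/2/13 ns -> greedy keeps 1 ns, skips 2 ns, takes 13 ns
  confs2 <- rep(list(far), 13)
  confs2[c(1, 2, 13)] <- list(tpl, tpl, tpl)
  ens2 <- ensemble_from_conformers(confs2, tpf = 1000)
  expect_equal(cluster_by_rmsd(ens2, tpl, spacing_ns = 5), c(1L, 13L))
  # a rigidly transformed copy of the reference is a candidate
  set.seed(2)
  moved <- rigid_move_conformer(tpl)
  ens3 <- ensemble_from_conformers(list(moved), tpf = 1000)
  expect_equal(cluster_by_rmsd(ens3, tpl), 1L)
  # uniform rigid motion of the whole ensemble does not change selections
  ens4 <- ens2
  n_at <- dim(ens4$coords)[1]
  flat <- do.call(rbind, lapply(seq_len(n_frames(ens4)),
                                function(i) ens4$coords[, , i]))
  flat <- random_rigid_motion(flat)
  for (i in seq_len(n_frames(ens4)))
    ens4$coords[, , i] <- flat[(i - 1) * n_at + seq_len(n_at), ]
  expect_equal(cluster_by_rmsd(ens4, tpl, spacing_ns = 5), c(1L, 13L))
  expect_error(cluster_by_rmsd(ens2, tpl, cutoff = 0), "positive")
})

test_that("scatter tables are one unbinned row per frame", {
  met <- fake_metrics(hb1 = rep(10, 7))
  met$plane_angle <- seq(0, 180, length.out = 7)
  tab <- scatter_table(met, "d", "plane_angle")
  expect_equal(nrow(tab), 7)
  expect_equal(tab$y, met$plane_angle)
  expect_error(scatter_table(met, "d", "not_a_metric"), "unknown metric")
})
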