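test_that("module summaries average member TPM on the linear scale", {
  prof <- data.frame(
    transcript_id = c("a", "b", "c"),
    p_med = log2(c(10, 30, 5)),
    i_med = log2(c(20, 60, 5)),
    r_med = log2(c(15, 45, 5)),
    stringsAsFactors = FALSE
  )
  asg <- c(a = 1L, b = 1L, c = 3L)
  s <- summarize_modules(asg, prof, n_modules = 4)
  expect_equal(s$p_bar[1], 20)   # mean(10, 30)
  expect_equal(s$i_bar[1], 40)   # mean(20, 60)
  expect_equal(s$n_transcripts, c(2L, 0L, 1L, 0L))
  # single-transcript module equals the transcript itself
  expect_equal(unlist(s[3, c("p_bar", "i_bar", "r_bar")],
                      use.names = FALSE), c(5, 5, 5))
  # empty module carries undefined means
  expect_true(is.na(s$p_bar[2]))

  # log2 scale: geometric mean of member TPM
  g <- summarize_modules(asg, prof, n_modules = 4, scale = "log2")
  expect_equal(g$p_bar[1], sqrt(10 * 30))
})

test_that("the four selection rules match their worked examples", {
  s <- data.frame(module_id = 1:3, n_transcripts = c(5L, 5L, 5L),
                  p_bar = c(10, 10, 40),
                  i_bar = c(40, 10, 10),
                  r_bar = c(25, 10, 10))
  # log2(40/10)=2 and log2(25/10)=1.32 -> ischemia-up
  expect_equal(apply_criterion(s, "ischemia", "up"), c(TRUE, FALSE, FALSE))
  # flat module selects nowhere
  flat <- s[2, ]
  for (eff in c("ischemia", "reperfusion")) {
    for (dir in c("up", "down")) {
      expect_false(apply_criterion(flat, eff, dir))
    }
  }
  # log2(10/40) = -2 twice -> ischemia-down
  expect_equal(apply_criterion(s, "ischemia", "down"), c(FALSE, FALSE, TRUE))
})

test_that("literal printed down-rule is available behind a flag", {
  s <- data.frame(module_id = 1L, n_transcripts = 1L,
                  p_bar = 10, i_bar = 10, r_bar = 10)
  # a flat module trivially satisfies log2-ratio <= +1
  expect_true(apply_criterion(s, "ischemia", "down", literal_table1 = TRUE))
  expect_false(apply_criterion(s, "ischemia", "down"))
})

test_that("zero or undefined module means are excluded with a warning", {
  s <- data.frame(module_id = 1:2, n_transcripts = c(3L, 0L),
                  p_bar = c(0, NA), i_bar = c(5, NA), r_bar = c(5, NA))
  expect_warning(res <- apply_criterion(s, "ischemia", "up"), "zero mean")
  expect_equal(res, c(FALSE, FALSE))
})

test_that("up and down rules for one effect are mutually exclusive", {
  set.seed(41)
  s <- data.frame(module_id = 1:200, n_transcripts = 1L,
                  p_bar = exp(rnorm(200, 3)),
                  i_bar = exp(rnorm(200, 3)),
                  r_bar = exp(rnorm(200, 3)))
  for (eff in c("ischemia", "reperfusion")) {
    up <- apply_criterion(s, eff, "up")
    down <- apply_criterion(s, eff, "down")
    expect_false(any(up & down))
  }
})

test_that("cluster assembly unions modules and reports overlaps", {
  s <- data.frame(module_id = 1:4, n_transcripts = c(2L, 1L, 1L, 0L),
                  p_bar = c(10, 10, 10, NA),
                  i_bar = c(40, 45, 10, NA),
                  r_bar = c(25, 30, 10, NA))
  asg <- c(t1 = 1L, t2 = 1L, t3 = 2L, t4 = 3L)
  out <- assemble_clusters(s, asg)
  c1 <- out$clusters$C1_ischemia_up
  expect_equal(c1$module_ids, c(1L, 2L))
  expect_setequal(c1$transcript_ids, c("t1", "t2", "t3"))
  expect_equal(c1$n_genes, 3L)
  expect_equal(out$clusters$C2_ischemia_down$n_genes, 0L)
  expect_equal(nrow(out$overlap), 0)

  # a module passing an ischemia AND a reperfusion rule lands in both
  s2 <- data.frame(module_id = 1L, n_transcripts = 1L,
                   p_bar = 10, i_bar = 40, r_bar = 160)
  out2 <- assemble_clusters(s2, c(x = 1L))
  expect_equal(out2$clusters$C1_ischemia_up$module_ids, 1L)
  expect_equal(out2$clusters$C3_reperfusion_up$module_ids, 1L)
  expect_equal(out2$overlap$module_id, 1L)

  # C1/C2 and C3/C4 can never intersect
  expect_length(intersect(out$clusters$C1_ischemia_up$module_ids,
                          out$clusters$C2_ischemia_down$module_ids), 0)
})

test_that("no module passing any rule yields four empty clusters", {
  s <- data.frame(module_id = 1:3, n_transcripts = 1L,
                  p_bar = c(10, 20, 30), i_bar = c(10, 20, 30),
                  r_bar = c(10, 20, 30))
  out <- assemble_clusters(s, c(a = 1L, b = 2L, c = 3L))
  expect_true(all(vapply(out$clusters, function(cl) cl$n_genes, integer(1))
                  == 0L))
})

test_that("cluster trajectories are scaled to the pre-ischemia baseline", {
  prof <- data.frame(transcript_id = c("x", "y"),
                     p_med = log2(c(10, 7)),
                     i_med = log2(c(40, 7)),
                     r_med = log2(c(20, 7)),
                     stringsAsFactors = FALSE)
  clusters <- list(
    C1_ischemia_up = list(label = "C1_ischemia_up", module_ids = 1L,
                          transcript_ids = "x", n_genes = 1L),
    C2_ischemia_down = list(label = "C2_ischemia_down",
                            module_ids = integer(0),
                            transcript_ids = character(0), n_genes = 0L),
    C4_flatish = list(label = "C4_flatish", module_ids = 2L,
                      transcript_ids = "y", n_genes = 1L)
  )
  rep <- cluster_trajectory_report(clusters, prof)
  expect_equal(nrow(rep), 2)  # empty cluster omitted
  expect_equal(unlist(rep[rep$label == "C1_ischemia_up",
                          c("pre", "isch", "reper")], use.names = FALSE),
               c(1, 4, 2))
  expect_equal(unlist(rep[rep$label == "C4_flatish",
                          c("pre", "isch", "reper")], use.names = FALSE),
               c(1, 1, 1))
})

test_that("selection is invariant to transcript order and module renumbering", {
  set.seed(42)
  prof <- data.frame(transcript_id = sprintf("t%02d", 1:30),
                     p_med = rnorm(30, 4), i_med = rnorm(30, 5),
                     r_med = rnorm(30, 5), stringsAsFactors = FALSE)
  asg <- setNames(sample(1:5, 30, replace = TRUE), prof$transcript_id)
  s1 <- summarize_modules(asg, prof, 5)
  perm <- sample(30)
  s2 <- summarize_modules(asg[perm], prof[perm, ], 5)
  expect_equal(s1, s2)
  c1 <- assemble_clusters(s1, asg)$clusters
  # renumber modules 1..5 -> 6-old and remap the assignment
  relabel <- c(5L, 4L, 3L, 2L, 1L)
  asg_r <- setNames(relabel[asg], names(asg))
  s_r <- summarize_modules(asg_r, prof, 5)
  c_r <- assemble_clusters(s_r, asg_r)$clusters
  for (lab in names(c1)) {
    expect_setequal(c1[[lab]]$transcript_ids, c_r[[lab]]$transcript_ids)
  }
})
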