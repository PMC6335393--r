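test_that("the relative-contact ratio gates edges as specified", {
  # N_ik = 2 of 100 input contacts at R = 0.01 -> connected
  contacts <- data.frame(pre = c("i", "x"), post = c("k", "i"), n = c(2, 100))
  e <- suppressWarnings(infer_connections(contacts, connection_criteria(13, 0.01)))
  expect_true(any(e$pre == "i" & e$post == "k"))
  # N_ik = 1 of 1000 -> not connected
  contacts2 <- data.frame(pre = c("i", "x"), post = c("k", "i"), n = c(1, 1000))
  e2 <- suppressWarnings(infer_connections(contacts2, connection_criteria(13, 0.01)))
  expect_false(any(e2$pre == "i" & e2$post == "k"))
  expect_error(infer_connections(data.frame(pre = "a", post = "b", n = -2)),
               "negative")
})

test_that("zero input contacts suppress outgoing edges with a warning", {
  contacts <- data.frame(pre = "i", post = "k", n = 50)  # i receives nothing
  expect_warning(e <- infer_connections(contacts, connection_criteria()),
                 "zero input contacts")
  expect_equal(nrow(e), 0L)
})

test_that("the input denominator allows more than 1/R downstream partners", {
  # neuron "hub" receives 100 input contacts and touches 150 targets;
  # with R = 0.01 an output denominator could keep at most 99 of them
  targets <- sprintf("t%03d", 1:150)
  contacts <- rbind(
    data.frame(pre = "hub", post = targets, n = 2),       # 300 output
    data.frame(pre = "src", post = "hub", n = 100),       # 100 input
    data.frame(pre = "hub", post = "src", n = 2))
  e <- suppressWarnings(infer_connections(contacts, connection_criteria(13, 0.01)))
  out_deg <- sum(e$pre == "hub")   # each ratio 2/100 = 0.02 > 0.01
  expect_gt(out_deg, 1 / 0.01)
  # with the output denominator the same table could keep none:
  # 2/302 = 0.0066 < 0.01 for every target
  expect_lt(2 / 302, 0.01)
})

test_that("edges are monotone in the contact criterion R", {
  cn <- synth_connectome(150, connectivity = 0.02, seed = 5)
  r_grid <- c(0.001, 0.005, 0.01, 0.05, 0.2)
  edge_sets <- lapply(r_grid, function(r) {
    e <- suppressWarnings(infer_connections(cn$contacts,
                                            connection_criteria(13, r),
                                            neuron_ids = cn$neurons$id))
    paste(e$pre, e$post)
  })
  for (i in seq_len(length(r_grid) - 1))
    expect_true(all(edge_sets[[i + 1]] %in% edge_sets[[i]]))
})

test_that("ROC scan scores perfect and random predictors correctly", {
  cn <- synth_connectome(120, connectivity = 0.02, seed = 8)
  ids <- cn$neurons$id
  ref <- cn$adjacency   # thresholded at (13, 0.01) by construction
  scan <- roc_scan(list(`13` = cn$contacts), r_grid = c(0.005, 0.01, 0.05),
                   reference = ref, neuron_ids = ids)
  expect_true(all(scan$table$tpr >= 0 & scan$table$tpr <= 1))
  expect_true(all(scan$table$fpr >= 0 & scan$table$fpr <= 1))
  at_ref <- scan$table[scan$table$r == 0.01, ]
  expect_equal(at_ref$tpr, 1)
  expect_equal(at_ref$fpr, 0)
  expect_error(roc_scan(list(`13` = cn$contacts), 0.01,
                        ref[0, ], ids), "empty reference")

  # random assignment at matched density: TPR ~ FPR (the diagonal)
  set.seed(1)
  n <- length(ids); npairs <- n * (n - 1); npos <- nrow(ref)
  diffs <- replicate(20, {
    pick <- sample(npairs, nrow(ref))
    pre_i <- (pick - 1) %/% (n - 1) + 1
    off <- (pick - 1) %% (n - 1) + 1
    post_i <- ifelse(off >= pre_i, off + 1, off)
    key <- paste(ids[pre_i], ids[post_i], sep = "\r")
    refkey <- paste(ref$pre, ref$post, sep = "\r")
    tp <- sum(key %in% refkey)
    tpr <- tp / npos
    fpr <- (length(key) - tp) / (npairs - npos)
    tpr - fpr
  })
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("the scan recovers the generating criteria as optimal", {
  sks <- synth_skeletons(25, seed = 13, box = 60)
  labs <- lapply(sks, attr, "truth_nodes")
  names(sks) <- names(labs) <- sprintf("n%02d", seq_along(sks))
  cbd <- lapply(c(`5` = 5, `13` = 13, `25` = 25), function(d)
    contact_matrix(sks, labs, max_distance = d))
  ref <- suppressWarnings(infer_connections(cbd[["13"]],
                                            connection_criteria(13, 0.01),
                                            neuron_ids = names(sks)))
  expect_gt(nrow(ref), 5)
  scan <- roc_scan(cbd, r_grid = c(0.002, 0.01, 0.05), reference = ref,
                   neuron_ids = names(sks))
  expect_equal(scan$best$distance, 13)
  expect_equal(scan$best$r, 0.01)
  expect_equal(scan$best$tpr, 1)
  expect_equal(scan$best$fpr, 0)
})
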