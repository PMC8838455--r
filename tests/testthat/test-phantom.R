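test_that("phantom generation is seeded and anatomically layered", {
  spec <- phantom_spec(shape = c(48, 48), seed = 11)
  ph1 <- make_phantom(spec)
  ph2 <- make_phantom(spec)
  expect_identical(ph1$t1_truth, ph2$t1_truth)
  expect_identical(ph1$label_map, ph2$label_map)

  lab <- ph1$label_map
  expect_setequal(sort(unique(as.integer(lab))), 0:4)
  # truths positive inside the brain, zero outside
  expect_true(all(ph1$t1_truth[lab != 0] > 0))
  expect_true(all(ph1$t1_truth[lab == 0] == 0))
  expect_true(all(ph1$t2s_truth[lab != 0] > 0))
  # the physical exclusion holds voxel-wise
  inb <- lab != 0
  expect_true(all(ph1$t1_truth[inb] >= ph1$t2s_truth[inb]))
  # B1+ field within its configured range inside the brain
  expect_true(all(ph1$b1_truth[inb] >= 0.9 - 1e-9 & ph1$b1_truth[inb] <= 1.1 + 1e-9))
})

test_that("lesions are placed only inside white matter", {
  ph <- make_phantom(phantom_spec(shape = c(64, 64), lesion_count = 3, seed = 4))
  les <- which(ph$label_map == ph$labels[["lesion"]], arr.ind = TRUE)
  expect_gt(nrow(les), 0)
  # every lesion voxel's 4-neighbourhood is WM or lesion (never GM/CSF/background)
  for (r in seq_len(nrow(les))) {
    i <- les[r, 1]; j <- les[r, 2]
    nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    vals <- ph$label_map[nb]
    expect_true(all(vals %in% c(ph$labels[["WM"]], ph$labels[["lesion"]])))
  }
})

test_that("per-tissue truth distributions match their configured moments", {
  ph <- make_phantom(phantom_spec(shape = c(96, 96), seed = 21))
  tv <- phantom_tissue_defaults()
  for (i in seq_len(nrow(tv))) {
    vox <- which(ph$label_map == ph$labels[[tv$tissue[i]]])
    if (length(vox) < 30) next
    se1 <- tv$t1_sd_ms[i] / sqrt(length(vox))
    expect_lt(abs(mean(ph$t1_truth[vox]) - tv$t1_mean_ms[i]), 5 * se1 + 1e-9)
    se2 <- tv$t2s_sd_ms[i] / sqrt(length(vox))
    # T2* is clipped at T1 for physical consistency; allow a one-sided margin
    expect_lt(abs(mean(ph$t2s_truth[vox]) - tv$t2s_mean_ms[i]), 5 * se2 + 1)
  }
  # GM truth centered near its configured 1286 ms
  gm <- ph$t1_truth[ph$label_map == ph$labels[["GM"]]]
  expect_lt(abs(mean(gm) - 1286), 10)
  # lesion T2* centered near its configured 86 ms
  ls <- ph$t2s_truth[ph$label_map == ph$labels[["lesion"]]]
  expect_lt(abs(mean(ls) - 86), 14)
})

test_that("a noise-free rendered stack matches back to the nearest grid truth", {
  sch <- make_schedule()
  # grid-aligned truth: overwrite the phantom truths with dictionary values
  dict <- fix_tiny_dictionary()
  ph <- make_phantom(phantom_spec(shape = c(16, 16), b1_range = c(1, 1), seed = 2))
  inb <- which(ph$label_map != 0)
  withr::with_seed(3, rows <- sample.int(nrow(dict$params), length(inb), replace = TRUE))
  ph$t1_truth[inb] <- dict$params$t1_ms[rows]
  ph$t2s_truth[inb] <- dict$params$t2s_ms[rows]
  ph$b1_truth[inb] <- 1
  stack <- render_stack(ph, sch, noise = "none")
  res <- match_stack(stack, dict)
  expect_equal(res$t1_map[inb], ph$t1_truth[inb])
  expect_equal(res$t2s_map[inb], ph$t2s_truth[inb])
  # and the residual bank of a noise-free stack is empty of energy
  nb <- extract_noise_bank(stack, dict)
  expect_lt(max(abs(nb$bank$residuals)), 1e-9)
})

test_that("gaussian rendering hits the target SNR in expectation", {
  sch <- make_schedule()
  ph <- make_phantom(phantom_spec(shape = c(48, 48), seed = 5))
  stack <- render_stack(ph, sch, noise = "gaussian", target_snr_db = 20, seed = 9)
  inb <- which(ph$label_map != 0)
  expect_gte(length(inb), 1000)
  sig <- simulate_fingerprints(
    sch, cbind(ph$t1_truth[inb], ph$t2s_truth[inb], ph$b1_truth[inb])
  )
  sig <- sig / sqrt(rowSums(sig^2))
  flat <- matrix(stack$data, prod(dim(ph$label_map)), 35)
  noise <- flat[inb, ] - sig
  snr <- 10 * log10(rowSums(sig^2) / rowSums(noise^2))
  expect_lt(abs(mean(snr) - 20), 1)
  # seeded determinism of the rendering
  stack2 <- render_stack(ph, sch, noise = "gaussian", target_snr_db = 20, seed = 9)
  expect_identical(stack$data, stack2$data)
})

test_that("bank and student-t noise modes are calibrated too", {
  sch <- make_schedule()
  ph <- make_phantom(phantom_spec(shape = c(24, 24), seed = 6))
  bank <- fix_gaussian_bank(snr_db = 20, n = 400)
  for (mode in c("bank", "student_t")) {
    stack <- render_stack(ph, sch, noise = mode, target_snr_db = 20,
                          bank = bank, seed = 3)
    inb <- which(ph$label_map != 0)
    sig <- simulate_fingerprints(
      sch, cbind(ph$t1_truth[inb], ph$t2s_truth[inb], ph$b1_truth[inb])
    )
    sig <- sig / sqrt(rowSums(sig^2))
    flat <- matrix(stack$data, prod(dim(ph$label_map)), 35)
    noise <- flat[inb, ] - sig
    snr <- 10 * log10(rowSums(sig^2) / rowSums(noise^2))
    expect_lt(abs(mean(snr) - 20), 1.5)
  }
  expect_error(render_stack(ph, sch, noise = "bank"), "bank")
})

test_that("phantom masks partition the slice", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32), seed = 7))
  masks <- phantom_masks(ph)
  expect_setequal(names(masks), c("GM", "WM", "CSF", "lesion", "brain"))
  summed <- masks$GM + masks$WM + masks$CSF + masks$lesion
  expect_equal(summed, masks$brain)
  expect_true(all(summed %in% c(0L, 1L)))
})
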