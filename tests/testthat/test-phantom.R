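tissues <- default_tissues()
scr <- sequence_params(4000, 7.26, 650, 2220, 5, 4, 180, 60)

test_that("noiseless phantom voxels carry the simulator signals exactly", {
  spec <- phantom_spec(dim = c(24, 24, 24), b1_range = c(1, 1), sigma = 0)
  ph <- generate_phantom(spec, scr, tissues)
  for (t in c("WM", "GM", "CSF")) {
    truth <- simulate_steady_state(scr, tissues[[t]])
    expect_true(all(abs(ph$inv1$data[ph$masks[[t]]] - Mod(truth$S1)) <
                      1e-14))
    expect_true(all(abs(ph$inv2$data[ph$masks[[t]]] - Mod(truth$S2)) <
                      1e-14))
  }
  expect_equal(unique(ph$inv1$data[ph$masks$BG]), 0)
})

test_that("labels partition the volume and masks avoid boundaries", {
  spec <- phantom_spec(dim = c(20, 20, 20))
  lab <- flawsopt:::phantom_labels(spec)
  expect_equal(sum(lab == "WM") + sum(lab == "GM") + sum(lab == "CSF") +
                 sum(lab == "BG"), prod(spec$dim))
  ph <- generate_phantom(phantom_spec(dim = c(20, 20, 20), sigma = 0,
                                      b1_range = c(1, 1)), scr, tissues)
  for (t in c("WM", "GM", "CSF"))
    expect_true(all(ph$labels[ph$masks[[t]]] == t))
  expect_lt(sum(ph$masks$WM), sum(ph$labels == "WM"))  # eroded
})

test_that("seeded phantom generation is bit-reproducible", {
  spec <- phantom_spec(dim = c(16, 16, 16), sigma = 0.001, seed = 77)
  a <- generate_phantom(spec, scr, tissues)
  b <- generate_phantom(spec, scr, tissues)
  expect_identical(a$inv1$data, b$inv1$data)
  expect_identical(a$inv2$data, b$inv2$data)
})

test_that("NIfTI round trip preserves voxels and spacing bit-exactly", {
  spec <- phantom_spec(dim = c(12, 12, 12), sigma = 0.0005)
  ph <- generate_phantom(spec, scr, tissues)
  f <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(ph$inv2, f)
  back <- read_nifti_volume(f)
  expect_identical(dim(back$data), dim(ph$inv2$data))
  expect_identical(as.vector(back$data), as.vector(ph$inv2$data))
  expect_equal(back$spacing, ph$inv2$spacing, tolerance = 1e-6)
  unlink(f)
  expect_error(read_nifti_volume(tempfile()), "not found")
  junk <- tempfile(fileext = ".nii")
  writeLines("this is not a nifti volume", junk)
  suppressWarnings(expect_error(read_nifti_volume(junk), "NIfTI"))
  unlink(junk)
})

test_that("image CNR reproduces its closed form on synthetic Gaussians", {
  set.seed(31)
  d <- c(10, 10, 10)
  img <- array(rnorm(prod(d), mean = 5, sd = 0.5), d)
  uni_img <- array(rnorm(prod(d), mean = 0.3, sd = 0.1), d)
  mask_a <- array(rep(c(TRUE, FALSE), each = 500), d)
  mask_b <- !mask_a
  wm <- array(TRUE, d)
  got <- estimate_image_cnr(img, mask_a, mask_b, uni_img, wm)
  want <- (mean(img[mask_a]) - mean(img[mask_b])) /
    mad(uni_img, constant = 1)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(estimate_image_cnr(img, mask_a, mask_a, uni_img, wm), 0)
  # common rescaling of contrast and reference leaves the CNR unchanged
  expect_equal(estimate_image_cnr(3 * img, mask_a, mask_b,
                                  array(3 * uni_img, d), wm),
               got, tolerance = 1e-12)
  expect_error(estimate_image_cnr(img, array(FALSE, d), mask_b, uni_img,
                                  wm), "empty")
})

test_that("contrast ratios are scale-free percentages of the UNI WM signal", {
  d <- c(8, 8, 8)
  img <- array(2, d); img[1:4, , ] <- 5
  uni_img <- array(0.4, d)
  a <- array(FALSE, d); a[1:4, , ] <- TRUE
  got <- contrast_ratio(img, a, !a, uni_img, array(TRUE, d))
  expect_equal(got, 100 * 3 / 0.4)
  expect_equal(contrast_ratio(img, a, a, uni_img, array(TRUE, d)), 0)
  expect_equal(contrast_ratio(array(2 * img, d), a, !a,
                              array(2 * uni_img, d), array(TRUE, d)),
               got)
})

test_that("phantom image CNR agrees with the Monte-Carlo engine", {
  sigma <- calibrate_sigma(scr, tissues)
  spec <- phantom_spec(dim = c(26, 26, 26), b1_range = c(1, 1),
                       sigma = sigma, seed = 8)
  ph <- generate_phantom(spec, scr, tissues)
  s1 <- ph$inv1$data * ph$inv1$polarity
  s2 <- ph$inv2$data * ph$inv2$polarity
  u <- uni(s1, s2)
  wm <- u[ph$masks$WM]
  gm <- u[ph$masks$GM]
  img_cnr <- (mean(wm) - mean(gm)) / sqrt(var(wm) + var(gm))
  nm <- noise_model(sigma = sigma, n_reps = 100000)
  eng <- mc_contrast_cnr(simulate_steady_state(scr, tissues$WM),
                         simulate_steady_state(scr, tissues$GM), "uni", nm)
  se <- sqrt((1 + img_cnr^2 / 2) * (1 / length(wm) + 1 / length(gm)))
  expect_lt(abs(img_cnr - eng), 3 * se)
})

test_that("WM is darker than GM in the FLAWS_min phantom image", {
  spec <- phantom_spec(dim = c(20, 20, 20), b1_range = c(1, 1), sigma = 0)
  ph <- generate_phantom(spec, scr, tissues)
  fm <- combine_volume(ph$inv1, ph$inv2, "flaws_min",
                       combiner_config(beta = 0))
  expect_lt(mean(fm$data[ph$masks$WM]), mean(fm$data[ph$masks$GM]))
})

test_that("raising alpha2 trades UNI GM-CSF against FLAWS_min GM-WM", {
  ratios <- lapply(c(4, 7), function(a2) {
    s <- scr; s$alpha2 <- a2
    ph <- generate_phantom(phantom_spec(dim = c(20, 20, 20),
                                        b1_range = c(1, 1), sigma = 0),
                           s, tissues)
    u <- combine_volume(ph$inv1, ph$inv2, "uni")
    fm <- combine_volume(ph$inv1, ph$inv2, "flaws_min",
                         combiner_config(beta = 0))
    # shift UNI to a positive range before forming percent ratios, as on
    # scanner-exported magnitude-style images
    us <- image_volume(u$data + 0.5)
    list(uni_gm_csf = contrast_ratio(us, ph$masks$GM, ph$masks$CSF, us,
                                     ph$masks$WM),
         flaws_gm_wm = contrast_ratio(fm, ph$masks$GM, ph$masks$WM, us,
                                      ph$masks$WM))
  })
  expect_gt(ratios[[2]]$uni_gm_csf, ratios[[1]]$uni_gm_csf)
  expect_lt(ratios[[2]]$flaws_gm_wm, ratios[[1]]$flaws_gm_wm)
})

test_that("image-path CNR ordering follows the protocol TR ordering", {
  sigma <- calibrate_sigma(scr, tissues)
  # common random numbers: the same noise field under each protocol
  cnrs <- sapply(list(c(4000, 4), c(4500, 6), c(5000, 7)), function(p) {
    s <- sequence_params(p[1], 7.26, 650, 2220, 5, p[2], 180, 60)
    ph <- generate_phantom(phantom_spec(dim = c(26, 26, 26),
                                        b1_range = c(1, 1), sigma = sigma,
                                        seed = 21), s, tissues)
    u <- uni(ph$inv1$data * ph$inv1$polarity,
             ph$inv2$data * ph$inv2$polarity)
    estimate_image_cnr(image_volume(u), ph$masks$WM, ph$masks$GM,
                       image_volume(u), ph$masks$WM)
  })
  expect_true(cnrs[1] < cnrs[2] && cnrs[2] < cnrs[3])
})
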