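test_that("severity params enforce the ordinal structure", {
  expect_error(severity_params(lesion_area_fracs = c(0, 0.2, 0.1, 0.3)),
               "non-decreasing")
  expect_error(severity_params(border_irregularity = c(0, 0.2, 0.3, 1.2)),
               "border_irregularity")
  expect_error(severity_params(lesion_area_fracs = c(0, 0.2, 0.3, 1.5)),
               "lesion_area_fracs")
  p <- severity_params(n_per_class = 3, seed = 2)
  expect_s3_class(p, "severity_params")
  ov <- severity_params(preset = "overlapping")
  expect_true(all(diff(ov$lesion_area_fracs) >= 0))
  expect_lt(ov$lesion_area_fracs[3] - ov$lesion_area_fracs[2],
            severity_params()$lesion_area_fracs[3] - severity_params()$lesion_area_fracs[2])
})

test_that("rendering respects class morphology and is deterministic", {
  p <- severity_params(n_per_class = 1, seed = 3)
  r0 <- render_image(0, p, seed = 10)
  expect_equal(sum(r0$mask), 0)
  expect_true(all(r0$pixels >= 0 & r0$pixels <= 1))
  expect_equal(dim(r0$pixels), c(64, 64, 3))

  a <- render_image(2, p, seed = 42)
  b <- render_image(2, p, seed = 42)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)
  expect_identical(dim(a$mask), dim(a$pixels)[1:2])

  expect_error(render_image(4, p), "class_index")
  expect_error(render_image(3, severity_params(image_size = 16)), "too small")
})

test_that("lesion area and boundary irregularity increase with class", {
  p <- severity_params(seed = 9)
  boundary_ratio <- function(mask) {
    # isoperimetric ratio from 4-neighbor boundary pixels
    m <- mask == 1
    up <- rbind(m[-1, ], FALSE); dn <- rbind(FALSE, m[-nrow(m), ])
    lf <- cbind(m[, -1], FALSE); rt <- cbind(FALSE, m[, -ncol(m)])
    per <- sum(m & !(up & dn & lf & rt))
    per^2 / (4 * pi * sum(m))
  }
  areas <- matrix(0, 20, 3)
  irr <- matrix(0, 20, 3)
  for (i in 1:20) {
    for (k in 1:3) {
      r <- render_image(k, p, seed = 100 * k + i)
      areas[i, k] <- sum(r$mask)
      irr[i, k] <- boundary_ratio(r$mask)
    }
  }
  expect_true(all(diff(colMeans(areas)) > 0))
  expect_true(all(diff(colMeans(irr)) > 0))
  # class 3 masks strictly larger than class 1 masks on average and pairwise
  expect_true(all(areas[, 3] > areas[, 1]))
})

test_that("generated datasets are balanced, unique and reproducible", {
  p <- severity_params(n_per_class = 1, image_size = 32, seed = 4)
  ds <- generate_dataset(p)
  expect_length(ds$records, 4)
  expect_equal(sort(vapply(ds$records, function(r) r$label, integer(1))), 0:3)

  ds2 <- micro_records()
  labs <- vapply(ds2$records, function(r) r$label, integer(1))
  expect_equal(unname(table(labs)), rep(2L, 4), ignore_attr = TRUE)
  expect_false(anyDuplicated(ds2$manifest$image_id) > 0)
  ds3 <- generate_dataset(severity_params(n_per_class = 2, image_size = 32, seed = 5))
  expect_identical(ds2$manifest, ds3$manifest)
  expect_identical(ds2$records[[5]]$pixels, ds3$records[[5]]$pixels)
})

test_that("dataset files round-trip through the manifest", {
  dir <- withr::local_tempdir()
  p <- severity_params(n_per_class = 1, image_size = 32, seed = 6)
  ds <- generate_dataset(p, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_dataset(file.path(dir, "manifest.csv"))
  expect_equal(length(back$records), 4)
  expect_equal(back$records[[2]]$label, ds$records[[2]]$label)
  # 8-bit PNG quantization: pixels agree to 1/255
  expect_lt(max(abs(back$records[[2]]$pixels - ds$records[[2]]$pixels)), 1 / 254)
  expect_identical(back$records[[4]]$mask, ds$records[[4]]$mask)
})

test_that("stratified split preserves class proportions exactly", {
  manifest <- data.frame(image_id = sprintf("r%05d", 1:8000),
                         image_path = "", mask_path = "",
                         label = rep(0:3, each = 2000), split = "")
  out <- stratified_split(manifest, c(0.8, 0.1, 0.1), seed = 3)
  expect_equal(unname(table(out$split)[c("train", "val", "test")]),
               c(6400L, 800L, 800L), ignore_attr = TRUE)
  for (k in 0:3) {
    tab <- table(out$split[out$label == k])
    expect_equal(unname(tab[c("train", "val", "test")]), c(1600L, 200L, 200L),
                 ignore_attr = TRUE)
  }
  # partition: every record in exactly one split
  expect_false(anyNA(out$split))
  # determinism
  out2 <- stratified_split(manifest, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(out, out2)
})

test_that("largest-remainder allocation is exact on small classes", {
  manifest <- data.frame(image_id = sprintf("r%02d", 1:10), image_path = "",
                         mask_path = "", label = rep(1L, 10), split = "")
  out <- stratified_split(manifest, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(unname(table(out$split)[c("train", "val", "test")]),
               c(8L, 1L, 1L), ignore_attr = TRUE)
  tiny <- manifest[1:2, ]
  expect_warning(stratified_split(tiny, c(0.8, 0.1, 0.1), seed = 1),
                 "best-effort")
  expect_error(stratified_split(manifest, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("split assignments copy onto records", {
  ds <- micro_records(4)
  man <- stratified_split(ds$manifest, c(0.5, 0.25, 0.25), seed = 2)
  recs <- apply_split(ds$records, man)
  splits <- vapply(recs, function(r) r$split, character(1))
  expect_setequal(unique(splits), c("train", "val", "test"))
  expect_identical(splits, man$split[match(vapply(recs, function(r) r$image_id,
                                                  character(1)), man$image_id)])
})
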