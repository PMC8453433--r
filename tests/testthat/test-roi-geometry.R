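test_that("midline reflection is an exact involution", {
  set.seed(5)
  m <- array(runif(16 * 10 * 6) < 0.2, c(16, 10, 6))
  expect_identical(reflect_across_midline(reflect_across_midline(m)), m)
  # midline-adjacent columns swap (extent 16: columns 8 and 9)
  a <- array(FALSE, c(16, 10, 6)); a[8, 3, 2] <- TRUE
  expect_true(reflect_across_midline(a)[9, 3, 2])
  # symmetric masks are fixed points
  s <- a | reflect_across_midline(a)
  expect_identical(reflect_across_midline(s), s)
  expect_error(reflect_across_midline(array(FALSE, c(15, 10, 6))), "even")
})

test_that("exclusion zone respects anisotropic spacing (distance oracle)", {
  d <- c(11, 11, 7)
  les <- array(FALSE, d); les[6, 6, 4] <- TRUE
  ez <- exclusion_zone(les, pixdim = c(1, 1, 3), dist_mm = 2)
  expect_true(ez[7, 6, 4])     # in-plane neighbour at 1 mm: excluded
  expect_true(ez[7, 7, 4])     # diagonal at sqrt(2) mm: excluded
  expect_false(ez[6, 6, 5])    # through-plane at 3 mm: retained
  expect_false(ez[8, 6, 4])    # in-plane at 2 mm exactly: retained (inclusive)
  # brute-force oracle over the whole grid
  dist <- distance_to_mask(array(TRUE, d), les, c(1, 1, 3))
  expect_identical(as.vector(ez), dist < 2)
})

# build a one-subject world: WM slab with optional lesions per visit
slab_series <- function(lesions_by_visit, dim = c(16, 12, 6),
                        pixdim = c(1, 1, 3), tissue_override = NULL) {
  lab <- tissue_labels()
  nvis <- length(lesions_by_visit)
  tissues <- lapply(seq_len(nvis), function(i) {
    t <- array(lab[["wm"]], dim)
    t[lesions_by_visit[[i]]] <- lab[["lesion"]]
    if (!is.null(tissue_override[[i]]))
      t[tissue_override[[i]]] <- lab[["gm"]]
    t
  })
  make_series(tissues, lesions = lesions_by_visit, pixdim = pixdim)
}

test_that("overall NAWM is the all-visit intersection minus the 2 mm lesion zone", {
  d <- c(16, 12, 6)
  none <- array(FALSE, d)
  s <- slab_series(list(none, none))
  expect_true(all(compute_overall_nawm(s)))

  les <- array(FALSE, d); les[8, 6, 3] <- TRUE
  s <- slab_series(list(none, les))
  ov <- compute_overall_nawm(s)
  expect_false(ov[8, 6, 3]); expect_false(ov[9, 6, 3])
  expect_true(ov[8, 6, 4])                    # 3 mm through-plane

  # GM at a single visit removes the voxel
  gm1 <- array(FALSE, d); gm1[2, 2, 2] <- TRUE
  s <- slab_series(list(none, none), tissue_override = list(gm1, NULL))
  expect_false(compute_overall_nawm(s)[2, 2, 2])
})

test_that("pre-lesion ROI filters follow the worked examples", {
  d <- c(16, 12, 6)
  none <- array(FALSE, d)
  mk_event <- function(res_idx) {
    res <- array(FALSE, d); res[res_idx] <- TRUE
    list(residual_mask = res, first_seen_week = 8, lesion_id = "L1")
  }
  s <- slab_series(list(none, none, none))     # visits 0, 4, 8

  # 9 valid voxels -> rejected_size
  roi <- define_prelesion_roi(mk_event(cbind(3:11, 3, 2)), s)
  expect_equal(roi$status, "rejected_size")
  expect_equal(roi$n_voxels, 9L)

  # 30 valid voxels -> accepted
  idx30 <- as.matrix(expand.grid(3:12, 3:5, 2))
  roi <- define_prelesion_roi(mk_event(idx30), s)
  expect_equal(roi$status, "accepted")
  expect_equal(roi$n_voxels, 30L)

  # 15 voxels, 7 of them within 2 mm of a pre-existing lesion -> 8 remain
  les <- array(FALSE, d); les[8, 8, 2] <- TRUE
  s2 <- slab_series(list(les, les, les))
  near7 <- cbind(c(7, 9, 8, 8, 7, 7, 9), c(8, 8, 7, 9, 7, 9, 7), 2)  # < 2 mm
  far8 <- cbind(6:13, 11, 2)                                          # 3 mm
  roi <- define_prelesion_roi(mk_event(rbind(near7, far8)), s2)
  expect_equal(roi$status, "rejected_size")
  expect_equal(roi$n_voxels, 8L)
})

test_that("minimum retained distance honours the inclusive 2 mm rule", {
  # candidates at 1.0, 1.9, 2.0, 3.0 mm from a lesion voxel (0.1 mm grid)
  d <- c(60, 8, 8)
  les <- array(FALSE, d); les[5, 4, 4] <- TRUE
  res <- array(FALSE, d); res[c(15, 24, 25, 35), 4, 4] <- TRUE
  s <- slab_series(list(les, les), dim = d, pixdim = c(0.1, 0.1, 0.1))
  ev <- list(residual_mask = res, first_seen_week = 4, lesion_id = "L1")
  roi <- define_prelesion_roi(ev, s, min_voxels = 1L)
  expect_equal(roi$status, "accepted")
  expect_equal(roi$n_voxels, 2L)              # 2.0 and 3.0 mm survive
  dmin <- min(distance_to_mask(roi$mask, les, c(0.1, 0.1, 0.1)))
  expect_equal(dmin, 2.0)
})

test_that("pair construction trims by reflection and keeps exact mirrors", {
  d <- c(16, 12, 6)
  none <- array(FALSE, d)
  pre <- array(FALSE, d)
  pre[3:6, 4:6, 2:3] <- TRUE                  # 24 voxels, left side

  # contralateral side clean: pair is the mask and its mirror
  s <- slab_series(list(none, none))
  pair <- define_pair(pre, s, "L1")
  expect_equal(pair$qc_status, "accepted")
  expect_identical(pair$prelesion_mask, pre)
  expect_identical(pair$contralateral_mask, reflect_across_midline(pre))

  # lesion zone on the mirror side trims both masks to a mirrored set
  les <- array(FALSE, d)
  les[12, 5, 2] <- TRUE                       # inside the mirror region
  s2 <- slab_series(list(les, les))
  pair2 <- define_pair(pre, s2, "L1")
  expect_equal(pair2$qc_status, "accepted")
  expect_lt(pair2$n_voxels, 24L)
  expect_identical(reflect_across_midline(pair2$prelesion_mask),
                   pair2$contralateral_mask)
  expect_equal(sum(pair2$prelesion_mask), sum(pair2$contralateral_mask))

  # trimming below 10 voxels rejects the pair
  panel <- array(FALSE, d); panel[3:5, 4:6, 2] <- TRUE   # 9 voxels... enlarge
  panel[6, 4, 2] <- TRUE                                  # 10 voxels
  wall <- array(FALSE, d)
  wall[reflect_across_midline(panel)] <- TRUE
  wall[11, 5, 3] <- TRUE
  s3 <- slab_series(list(wall, wall))
  pair3 <- define_pair(panel, s3, "L1")
  expect_equal(pair3$qc_status, "rejected_size")
})

test_that("accepted pairs satisfy the mirror and size invariants; lesions only shrink ROIs", {
  cfg <- tiny_config(lesion_rate = 1, seed = 77)
  ms <- generate_ms_subject(cfg, "A", seed = 13)
  events <- find_lesion_events(ms)
  res <- derive_roi_pairs(ms, events)
  expect_gt(length(res$pairs), 0)
  for (p in res$pairs) {
    expect_identical(reflect_across_midline(p$prelesion_mask),
                     p$contralateral_mask)
    expect_gte(p$n_voxels, 10L)
  }
  # monotonicity: enlarging a lesion mask never enlarges any accepted ROI
  ms2 <- ms
  extra <- exclusion_zone(ms2$timepoints[[2]]$lesion_mask, ms2$pixdim, 1.5)
  ms2$timepoints[[2]]$lesion_mask <- ms2$timepoints[[2]]$lesion_mask | extra
  ms2$timepoints[[2]]$tissue[extra] <- tissue_labels()[["lesion"]]
  res2 <- derive_roi_pairs(ms2, events)
  n1 <- sum(vapply(res$pairs, `[[`, integer(1), "n_voxels"))
  n2 <- sum(vapply(res2$pairs, `[[`, integer(1), "n_voxels"))
  expect_lte(n2, n1)
})
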