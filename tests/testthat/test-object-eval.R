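# Object-based and pixel-wise evaluation.

test_that("extract_objects finds components with majority classes", {
  expect_equal(nrow(extract_objects(semantic_map(matrix(2L, 16, 16)))), 0)

  sm <- disk_semantic_map(classes = c(0L, 0L))
  objs <- extract_objects(sm, min_area_px = 10)
  expect_equal(nrow(objs), 2)
  expect_true(all(objs$class == "live"))
  expect_equal(objs$area_px, rep(sum(disk_mask(64, 64, 20, 20, 8)), 2))

  # 60% dead / 40% live pixels in one object: majority dead
  lab <- matrix(2L, 20, 20)
  lab[5:14, 5:10] <- 1L   # 60 px dead
  lab[5:12, 11:15] <- 0L  # 40 px live, 8-connected to the dead slab
  objs2 <- extract_objects(semantic_map(lab), min_area_px = 10)
  expect_equal(nrow(objs2), 1)
  expect_equal(objs2$class, "dead")
})

test_that("dominant_label votes inside the ground-truth pixel set", {
  gt <- disk_semantic_map(centers = list(c(20, 20)), classes = 1L)
  obj <- extract_objects(gt, min_area_px = 10)

  # identical prediction: the object's own class
  expect_equal(dominant_label(obj$pixels[[1]], gt), "dead")
  # background everywhere: missed
  expect_equal(dominant_label(obj$pixels[[1]], semantic_map(matrix(2L, 64, 64))),
               "missed")
  # 6 dead / 4 live among 10 object pixels: dead
  px <- obj$pixels[[1]][1:10]
  pred <- matrix(2L, 64, 64)
  pred[px[1:6]] <- 1L
  pred[px[7:10]] <- 0L
  expect_equal(dominant_label(px, semantic_map(pred)), "dead")
  # live/dead tie: dead
  pred[px[6]] <- 0L
  expect_equal(dominant_label(px, semantic_map(pred)), "dead")
  expect_error(dominant_label(integer(0), gt), class = "phaseviab_arg_error")
})

test_that("object_confusion matches its definition on simple scenes", {
  gt <- disk_semantic_map(classes = c(0L, 1L))
  cm <- object_confusion(gt, gt, min_area_px = 10)
  expect_equal(cm$counts, matrix(c(1L, 0L, 0L, 1L), 2, 2,
                                 dimnames = dimnames(cm$counts)))
  expect_equal(unname(cm$missed), c(0L, 0L))

  # all live objects predicted dead
  gt2 <- disk_semantic_map(classes = c(0L, 0L))
  pred2 <- disk_semantic_map(classes = c(1L, 1L))
  cm2 <- object_confusion(gt2, pred2, min_area_px = 10)
  expect_equal(cm2$counts["dead", "live"], 2L)
  expect_equal(cm2$n_live, 2L)
  expect_error(object_confusion(gt, semantic_map(matrix(2L, 8, 8))),
               class = "phaseviab_arg_error")
})

test_that("object_confusion equals an exhaustive brute-force tally", {
  for (seed in 1:25) {
    gt <- random_scene(seed)
    pred <- perturb_scene(gt, seed + 1000)
    got <- object_confusion(gt, pred, min_area_px = 1)
    want <- brute_object_confusion(gt, pred, min_area = 1)
    expect_equal(unclass(got$counts), unclass(want$counts))
    expect_equal(got$missed, want$missed)
  }
})

test_that("controlled label flips land in the expected confusion cells", {
  # 3x3 grid of live disks; flip a known subset to dead in the prediction
  centers <- expand.grid(r = c(12, 32, 52), c = c(12, 32, 52))
  centers <- lapply(seq_len(nrow(centers)),
                    function(i) c(centers$r[i], centers$c[i]))
  gt <- disk_semantic_map(h = 64, w = 64, r = 5, centers = centers,
                          classes = rep(0L, 9))
  flipped <- disk_semantic_map(h = 64, w = 64, r = 5, centers = centers,
                               classes = c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L))
  cm <- object_confusion(gt, flipped, min_area_px = 10)
  expect_equal(cm$counts["live", "live"], 6L)
  expect_equal(cm$counts["dead", "live"], 3L)
  expect_equal(cm$n_live, 9L)
})

test_that("normalized confusion reproduces the published normalization", {
  # 1949 of 1973 live called live -> 98.8% after table-style rounding
  counts <- matrix(c(1949L, 24L, 6L, 240L), 2, 2,
                   dimnames = list(pred = c("live", "dead"),
                                   gt = c("live", "dead")))
  norm <- normalize_confusion(counts)
  expect_equal(round_half_up(norm["live", "live"]), 98.8)
  expect_equal(colSums(norm), c(gt = 100, gt = 100), ignore_attr = TRUE)

  perfect <- matrix(c(5L, 0L, 0L, 3L), 2, 2,
                    dimnames = dimnames(counts))
  expect_equal(unname(normalize_confusion(perfect)),
               matrix(c(100, 0, 0, 100), 2, 2))
  expect_warning(normalize_confusion(matrix(c(1L, 0L, 0L, 0L), 2, 2)))
})

test_that("prf1 reproduces the published table arithmetic", {
  # dead column of the necrosis assay: P 91.2, R 97.6 -> F1 94.3
  expect_equal(round_half_up(f1_from_pr(91.2, 97.6)), 94.3)
  # live column of the apoptosis assay: P 94.6, R 90.1 -> F1 92.3
  expect_equal(round_half_up(f1_from_pr(94.6, 90.1)), 92.3)
  expect_equal(round_half_up(f1_from_pr(96.8, 98.3)), 97.5)
  expect_equal(f1_from_pr(100, 100), 100)
  # harmonic-mean fixed point
  expect_equal(f1_from_pr(73.5, 73.5), 73.5)
  expect_error(f1_from_pr(0, 0), class = "phaseviab_arg_error")

  # full report on a synthetic matrix; recall equals the normalized diagonal
  counts <- matrix(c(1949L, 24L, 6L, 240L), 2, 2,
                   dimnames = list(pred = c("live", "dead"),
                                   gt = c("live", "dead")))
  rep <- prf1(counts)
  norm <- normalize_confusion(counts)
  expect_equal(rep$recall_pct[rep$class == "live"], norm["live", "live"])
  expect_equal(rep$recall_pct[rep$class == "dead"], norm["dead", "dead"])
  expect_equal(rep$f1_pct[rep$class == "macro"],
               mean(rep$f1_pct[rep$class != "macro"]))
})

test_that("macro F1 is invariant to swapping classes in both maps", {
  gt <- random_scene(77)
  pred <- perturb_scene(gt, 78)
  swap <- function(m) {
    lab <- unclass(m)
    out <- lab
    out[lab == 0L] <- 1L
    out[lab == 1L] <- 0L
    semantic_map(out)
  }
  f1 <- function(g, p) {
    # degenerate one-class scenes trip prf1's zero-denominator flags, which
    # is by design and irrelevant to the symmetry being checked
    r <- suppressWarnings(prf1(object_confusion(g, p, min_area_px = 1)))
    r$f1_pct[r$class == "macro"]
  }
  expect_equal(f1(gt, pred), f1(swap(gt), swap(pred)))
})

test_that("pixel metrics count correctly on a hand-sized fixture", {
  gt <- semantic_map(matrix(c(0L, 0L, 1L, 2L,
                              0L, 1L, 1L, 2L,
                              2L, 2L, 2L, 2L,
                              0L, 1L, 2L, 2L), 4, 4, byrow = TRUE))
  pred <- semantic_map(matrix(c(0L, 1L, 1L, 2L,
                                0L, 1L, 2L, 2L,
                                2L, 2L, 2L, 2L,
                                0L, 1L, 2L, 2L), 4, 4, byrow = TRUE))
  pm <- pixel_metrics(gt, pred)
  # live: TP 3, FP 0, FN 1 -> P 100, R 75; dead: TP 3, FP 1, FN 1
  live <- pm[pm$class == "live", ]
  dead <- pm[pm$class == "dead", ]
  expect_equal(live$precision_pct, 100)
  expect_equal(live$recall_pct, 75)
  expect_equal(dead$precision_pct, 75)
  expect_equal(dead$recall_pct, 75)
  expect_equal(dead$iou_pct, 100 * 3 / 5)

  # identity: all 100
  pm_id <- pixel_metrics(gt, gt)
  expect_true(all(pm_id$f1_pct == 100))
  # live<->dead swap: live and dead recall 0
  swap <- unclass(gt)
  tmp <- swap
  tmp[swap == 0L] <- 1L; tmp[swap == 1L] <- 0L
  pm_sw <- pixel_metrics(gt, semantic_map(tmp))
  expect_equal(pm_sw$recall_pct[pm_sw$class %in% c("live", "dead")], c(0, 0))
})

test_that("tidiers summarize confusion objects", {
  gt <- disk_semantic_map(classes = c(0L, 1L))
  cm <- object_confusion(gt, gt, min_area_px = 10)
  td <- tidy(cm)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$n), 2L)
  gl <- glance(cm)
  expect_equal(gl$macro_f1_pct, 100)
})
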