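test_that("fifteen functional components merge into seven categories", {
  lm15 <- label_map("functional-15",
                    list("0" = c("VN1", "VN2"), "1" = "PCN", "2" = "SN",
                         "3" = c("L_CEN", "R_CEN"), "4" = c("SMN1", "AN")))
  lm7 <- combine_to_seven(lm15)
  expect_identical(lm7$scheme, "functional-7")
  expect_identical(hypercore:::labels_of(lm7, 0), "VN")   # dedup inside VN
  expect_identical(hypercore:::labels_of(lm7, 1), "DMN")  # PCN is posterior DMN
  expect_identical(hypercore:::labels_of(lm7, 2), "SN")
  expect_identical(hypercore:::labels_of(lm7, 3), "CEN")
  expect_setequal(hypercore:::labels_of(lm7, 4), c("SMN", "AN"))
  bad <- label_map("functional-15", list("0" = "VN1"))
  bad$membership[["0"]] <- "XXX"
  expect_error(combine_to_seven(bad), "unknown source label")
  expect_error(combine_to_seven(lm7), "functional-15")
})

test_that("core composition counts duplicates and normalises by core size", {
  labs <- label_map("functional-7",
                    c(stats::setNames(as.list(rep("DMN", 6)), as.character(0:5)),
                      stats::setNames(as.list(rep("VN", 2)), as.character(6:7))))
  prof <- kmaxcore_composition(0:9, labs, kmax = 12)
  expect_equal(prof$counts$DMN, 6)
  expect_equal(prof$counts$VN, 2)
  expect_equal(prof$fractions$DMN, 0.6)
  expect_equal(prof$fractions$VN, 0.2)
  expect_equal(prof$core_size, 10)

  labs2 <- label_map("functional-7", list("0" = c("DMN", "VN")))
  prof2 <- kmaxcore_composition(0:0, labs2, kmax = 3)
  expect_equal(prof2$counts$DMN, 1)
  expect_equal(prof2$counts$VN, 1)
  expect_gt(sum(unlist(prof2$fractions)), 1 - 1e-12)  # duplicates can exceed 1

  none <- kmaxcore_composition(0:4, label_map("functional-7", list()), 2)
  expect_true(all(unlist(none$counts) == 0))
  expect_error(kmaxcore_composition(integer(0), labs, 1), "empty core")
})

test_that("dominance classification follows the 40% rule", {
  mk <- function(dmn, vn) {
    fr <- stats::setNames(as.list(rep(0.05, 7)), scheme_labels("functional-7"))
    fr$DMN <- dmn; fr$VN <- vn
    structure(list(scheme = "functional-7", counts = list(),
                   fractions = fr, kmax = 1L, core_size = 10L,
                   pattern = NA_character_), class = "composition_profile")
  }
  expect_equal(classify_pattern(mk(0.60, 0.10))$pattern, "DMN-dominant")
  expect_equal(classify_pattern(mk(0.10, 0.45))$pattern, "VN-dominant")
  expect_equal(classify_pattern(mk(0.20, 0.20))$pattern, "distributed")
  expect_equal(classify_pattern(mk(0.40, 0.10))$pattern, "distributed") # strict >
  expect_equal(classify_pattern(mk(0.55, 0.45))$pattern, "DMN-dominant")
  expect_equal(classify_pattern(mk(0.45, 0.55))$pattern, "VN-dominant")
  expect_equal(classify_pattern(mk(0.50, 0.50))$pattern, "distributed") # tie
  wrong <- mk(0.6, 0.1); wrong$scheme <- "functional-15"
  expect_error(classify_pattern(wrong), "functional-7")
})

test_that("common core uses an inclusive share threshold", {
  cc <- common_core(list(c(1, 2, 3), c(1, 2), 1), share_fraction = 0.6)
  expect_setequal(cc$voxels, c(1, 2))      # counts 3 and 2 >= 1.8
  expect_equal(unname(cc$counts[c("1", "2", "3")]), c(3L, 2L, 1L))
  inter <- common_core(list(c(1, 2, 3), c(2, 3), c(2, 4)), share_fraction = 1)
  expect_identical(inter$voxels, 2L)
  expect_length(common_core(list(1:3, 4:6, 7:9), 0.6)$voxels, 0)
  # 18 of 30 subjects qualifies at exactly 60%
  cores30 <- c(replicate(18, c(7L, 9L), simplify = FALSE),
               replicate(12, 11L, simplify = FALSE))
  expect_setequal(common_core(cores30, 0.6)$voxels, c(7, 9))
  expect_error(common_core(list(1:3), 0.6), "at least 2")
})

test_that("higher share fractions give nested common cores", {
  set.seed(55)
  cores <- replicate(12, sample(0:60, 25), simplify = FALSE)
  fr <- c(0.3, 0.5, 0.7, 0.9)
  sets <- lapply(fr, function(f) common_core(cores, f)$voxels)
  for (i in seq_len(length(fr) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("core degree records come from the full graph", {
  g <- k4_pendant()
  d <- kcore_decomposition(g)
  labs <- simple_labels(0:4, c("DMN", "DMN", "VN", "VN", "VN"))
  rec <- kmaxcore_degree_histogram(d$kmax_core, g, labs)
  # node 0 touches the pendant: degree 4 in the original graph
  expect_setequal(rec$degree, c(4, 3, 3, 3))
  expect_gte(min(rec$degree), d$k_max)
  two <- kmaxcore_degree_histogram(c(0, 1),
                                   g, label_map("functional-7",
                                                list("0" = c("DMN", "VN"))))
  expect_equal(sum(two$voxel_id == 0), 2)
  expect_equal(unique(two$degree[two$voxel_id == 0]), 4)
  expect_equal(two$category[two$voxel_id == 1], "none")
  expect_error(kmaxcore_degree_histogram(c(0, 99), g, labs), "missing")
})

test_that("core degrees always dominate k_max on random graphs", {
  for (rep in 1:20) {
    g <- er_graph(sample(20:80, 1), runif(1, 0.1, 0.4), seed = 700 + rep)
    d <- kcore_decomposition(g)
    labs <- simple_labels(hypercore:::graph_ids(g),
                          rep("VN", igraph::vcount(g)))
    rec <- kmaxcore_degree_histogram(d$kmax_core, g, labs)
    expect_gte(min(rec$degree), d$k_max)
  }
})
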