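# Lignocellulose classification: watchlist, activity override, summaries.

test_that("the packaged class map holds 44 microbiota watchlist families: 33 GH + 8 CE + 3 AA", {
  map <- load_class_map()
  wl <- watchlist_families(map, scope = "microbiota")
  expect_equal(length(wl), 44L)
  cls <- table(cazy_class(wl))
  expect_equal(unname(cls[["GH"]]), 33L)
  expect_equal(unname(cls[["CE"]]), 8L)
  expect_equal(unname(cls[["AA"]]), 3L)
})

test_that("a malformed class map is fatal at load time", {
  bad <- data.frame(family = "GH5", class = "GH", roles = "not_a_role",
                    scope = "microbiota", is_lignocellulolytic_default = TRUE,
                    source = "curated")
  expect_error(load_class_map(write_tsv_tmp(bad)), "unknown role")
  bad2 <- bad; bad2$roles <- "hemicellulase"; bad2$family <- "XY9"
  expect_error(load_class_map(write_tsv_tmp(bad2)), "invalid family")
})

test_that("classification: watchlist membership, override, fallback, unresolved", {
  calls <- calls_df(c("o1", "o2", "o3", "o4", "o5"),
                    c("GH13", "GH5", "CE1", "GH5_13", "GH43"))
  acts <- data.frame(orf_id = c("o2", "o3", "o5"),
                     family = c("GH5", "CE1", "GH43"),
                     activity = c("cellulase", "chitinase", "mysterase"),
                     stringsAsFactors = FALSE)
  a <- classify_calls(calls, acts)
  expect_equal(a$substrate_class[a$orf_id == "o1"], "not_applicable") # GH13 off-list
  expect_equal(a$substrate_class[a$orf_id == "o2"], "lignocellulolytic")
  expect_equal(a$activity_source[a$orf_id == "o2"], "peptide_predictor")
  expect_equal(a$substrate_class[a$orf_id == "o3"], "other_substrate")
  # no prediction -> family default (most common activity), here lignocellulolytic
  expect_equal(a$substrate_class[a$orf_id == "o4"], "lignocellulolytic")
  expect_equal(a$activity_source[a$orf_id == "o4"], "family_default")
  # unmatched activity string -> unresolved, never guessed
  expect_equal(a$substrate_class[a$orf_id == "o5"], "unresolved")
})

test_that("override precedence is total and classes partition the watchlist calls", {
  set.seed(3)
  fams <- c("GH5", "GH43", "CE1", "AA1", "GH13", "GT2")
  calls <- calls_df(sprintf("o%03d", 1:120), sample(fams, 120, TRUE),
                    module_count = sample(1:2, 120, TRUE))
  with_act <- sample(calls$orf_id, 50)
  acts <- data.frame(orf_id = with_act,
                     family = calls$family[match(with_act, calls$orf_id)],
                     activity = sample(c("xylanase", "chitinase", "laccase"),
                                       50, TRUE))
  a <- classify_calls(calls, acts)
  w <- a[a$watchlist, ]
  expect_false(any(w$activity_source == "family_default" & !is.na(w$activity)))
  expect_true(all(w$substrate_class %in%
                    c("lignocellulolytic", "other_substrate", "unresolved")))
  expect_true(all(a$substrate_class[!a$watchlist] == "not_applicable"))
  s <- summarize_classes(a)
  expect_equal(sum(s$modules_by_class), s$n_watchlist_modules)
})

test_that("summary percentages cover predicted modules only, to one decimal", {
  # 8 predicted modules: 5 lignocellulolytic + 3 other; 4 unpredicted
  calls <- calls_df(sprintf("o%d", 1:12), "GH5")
  acts <- data.frame(orf_id = sprintf("o%d", 1:8), family = "GH5",
                     activity = c(rep("cellulase", 5), rep("chitinase", 3)))
  s <- summarize_classes(classify_calls(calls, acts))
  expect_equal(s$n_predicted_modules, 8L)
  expect_equal(s$pct_lignocellulolytic, round(100 * 5 / 8, 1))
  expect_equal(s$pct_other_substrate, round(100 * 3 / 8, 1))
  expect_equal(s$pct_lignocellulolytic + s$pct_other_substrate, 100)
  expect_equal(s$n_watchlist_modules, 12L)
})

test_that("with zero predicted modules the percentages are NA, not 0", {
  s <- summarize_classes(classify_calls(calls_df("o1", "GH5")))
  expect_true(is.na(s$pct_lignocellulolytic))
  expect_true(is.na(s$pct_other_substrate))
})

test_that("per-group breakdown counts families and modules by role", {
  meta <- mini_meta(ids = c("m1", "m2"), kinds = c("metagenome", "metagenome"),
                    n_orfs = c(1000L, 1000L))
  meta$tissue <- c("caeca", "hindgut")
  calls <- rbind(calls_df(c("o1", "o2"), c("GH5", "GH43"), sample_id = "m1"),
                 calls_df("o3", "AA1", sample_id = "m2"))
  s <- summarize_classes(classify_calls(calls), meta, by = "tissue")
  expect_true(is.data.frame(s$by_group))
  expect_equal(sum(s$by_group$n_modules), 3L)
  expect_setequal(unique(s$by_group$tissue), c("caeca", "hindgut"))
})

test_that("richness ratio compares a focal species to the mean of the others", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     host_species = c("aqua", "terr1", "terr2"),
                     origin = "field", sex = "female", tissue = "hindgut",
                     dataset_kind = "metagenome",
                     n_orfs = 1000L, stringsAsFactors = FALSE)
  calls <- rbind(
    calls_df(sprintf("a%d", 1:3), c("GH5", "GH43", "CE1"), sample_id = "a"),
    calls_df("b1", "GH5", sample_id = "b"),
    calls_df(c("c1", "c2", "c3"), c("GH5", "GH5_13", "GH43"), sample_id = "c"))
  r <- ligno_richness_ratio(classify_calls(calls), meta, "aqua")
  expect_equal(unname(r$richness[c("aqua", "terr1", "terr2")]), c(3L, 1L, 2L))
  expect_equal(r$ratio, round(3 / 1.5, 1))
})
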