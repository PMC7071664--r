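# Lignocellulose functional classification of consensus calls.
#
# A CAZy family can bring together enzymes with very different substrates,
# so membership of a lignocellulose "watchlist" family is only a prior: an
# explicit per-ORF activity prediction overrides it, and calls with no
# prediction fall back to the family's most common activity.

LIGNO_ROLES <- c("cellulase_endo", "cellulase_betaglucosidase",
                 "cellulase_phosphorylase", "cellulase_lpmo", "hemicellulase",
                 "lme_laccase", "lme_cdh", "lme_peroxidase", "other")

# Controlled activity vocabulary (matched case-insensitively after trimming).
.ligno_terms <- c(
  "cellulase", "endoglucanase", "endo-beta-1,4-glucanase",
  "cellobiohydrolase", "beta-glucosidase", "cellobiose phosphorylase",
  "lytic polysaccharide monooxygenase", "lpmo", "xylanase",
  "endo-1,4-beta-xylanase", "beta-xylosidase", "xyloglucanase", "mannanase",
  "beta-mannanase", "beta-mannosidase", "alpha-galactosidase",
  "beta-galactosidase", "arabinofuranosidase", "alpha-l-arabinofuranosidase",
  "alpha-glucuronidase", "licheninase", "acetyl xylan esterase",
  "feruloyl esterase", "glucuronoyl esterase", "laccase",
  "cellobiose dehydrogenase", "peroxidase", "manganese peroxidase",
  "lignin peroxidase", "alpha-fucosidase", "beta-1,3-xylosidase")
.other_terms <- c(
  "chitinase", "chitosanase", "lysozyme", "amylase", "alpha-amylase",
  "pullulanase", "pectinase", "pectate lyase", "pectin lyase",
  "polygalacturonase", "agarase", "sialidase", "trehalase", "invertase",
  "levanase", "inulinase", "dextranase", "alpha-glucosidase")

match_activity <- function(activity) {
  a <- tolower(trimws(as.character(activity)))
  out <- rep("unresolved", length(a))
  out[a %in% .ligno_terms] <- "lignocellulolytic"
  out[a %in% .other_terms] <- "other_substrate"
  out[is.na(a) | a == ""] <- NA_character_
  out
}

#' Load the lignocellulose family class map
#'
#' The packaged map assigns each watchlist CAZy family its functional
#' role(s) (endocellulase, beta-glucosidase, cellobiose phosphorylase, LPMO,
#' hemicellulase, laccase, cellobiose dehydrogenase), the compartment where
#' it was observed (`scope`: microbiota, host, or both) and whether its most
#' common activity is lignocellulolytic. The file is an ordinary TSV that
#' users can extend; `source` distinguishes families named in published
#' isopod CAZome results (`reported`) from standard hemicellulase family
#' assignments added to complete the list (`curated`).
#'
#' @param path optional path to a custom map; defaults to the packaged one.
#' @return validated data.frame of class `"cazy_class_map"`.
#' @export
load_class_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lignocellulose_families.tsv",
                        package = "cazomer", mustWork = TRUE)
  }
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "class", "roles", "scope",
            "is_lignocellulolytic_default", "source")
  if (!all(need %in% names(m))) {
    stop("class map must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is_cazy_label(m$family))) {
    stop("invalid family label(s) in class map: ",
         paste(m$family[!is_cazy_label(m$family)], collapse = ", "))
  }
  role_list <- strsplit(m$roles, ",", fixed = TRUE)
  if (any(lengths(role_list) == 0L)) {
    stop("every watchlist family needs at least one role")
  }
  bad_roles <- setdiff(unlist(role_list), LIGNO_ROLES)
  if (length(bad_roles)) {
    stop("unknown role(s) in class map: ", paste(bad_roles, collapse = ", "))
  }
  if (!all(m$scope %in% c("microbiota", "host", "both"))) {
    stop("scope must be one of microbiota, host, both")
  }
  if (anyDuplicated(m$family)) stop("duplicated family in class map")
  m$is_lignocellulolytic_default <- as.logical(m$is_lignocellulolytic_default)
  class(m) <- c("cazy_class_map", "data.frame")
  m
}

#' Watchlist families of a class map
#'
#' @param map a class map from [load_class_map()].
#' @param scope `"microbiota"` (families observed in microbiota, including
#'   shared ones), `"host"`, or `"all"`.
#' @return character vector of family labels.
#' @export
watchlist_families <- function(map, scope = c("microbiota", "host", "all")) {
  scope <- match.arg(scope)
  keep <- switch(scope,
                 microbiota = map$scope %in% c("microbiota", "both"),
                 host = map$scope %in% c("host", "both"),
                 all = rep(TRUE, nrow(map)))
  order_families(map$family[keep])
}

#' Classify consensus calls into lignocellulose functional classes
#'
#' Each call in a watchlist family is labelled `lignocellulolytic`,
#' `other_substrate` or `unresolved`; non-watchlist families are
#' `not_applicable`. An explicit activity prediction for the (ORF, family)
#' always overrides the family default (`activity_source =
#' "peptide_predictor"`); activity strings are matched against a small
#' controlled vocabulary, case-insensitively, and unmatched strings yield
#' `unresolved`, never a guess. Calls without a prediction take the family's
#' most common activity (`activity_source = "family_default"`).
#'
#' @param calls consensus calls ([call_consensus()]) or any data.frame with
#'   `orf_id`, `family`, `module_count`, `sample_id`.
#' @param activities optional data.frame of per-ORF activity predictions
#'   with columns `orf_id`, `family`, `activity`.
#' @param map class map from [load_class_map()].
#' @return the calls with added columns `watchlist`, `role`, `activity`,
#'   `activity_source`, `substrate_class`.
#' @export
classify_calls <- function(calls, activities = NULL, map = load_class_map()) {
  stopifnot(inherits(map, "cazy_class_map"))
  out <- as.data.frame(calls)
  fam <- canonical_family(out$family, level = "family")
  mi <- match(fam, map$family)
  out$watchlist <- !is.na(mi)
  out$role <- ifelse(out$watchlist, map$roles[mi], NA_character_)

  out$activity <- NA_character_
  if (!is.null(activities) && nrow(activities)) {
    stopifnot(all(c("orf_id", "family", "activity") %in% names(activities)))
    akey <- paste(activities$orf_id,
                  canonical_family(activities$family, level = "family"))
    ai <- match(paste(out$orf_id, fam), akey)
    out$activity <- activities$activity[ai]
  }
  has_pred <- out$watchlist & !is.na(out$activity)
  out$activity_source <- ifelse(!out$watchlist, NA_character_,
                                ifelse(has_pred, "peptide_predictor",
                                       "family_default"))

  out$substrate_class <- "not_applicable"
  out$substrate_class[out$watchlist] <- ifelse(
    map$is_lignocellulolytic_default[mi[out$watchlist]],
    "lignocellulolytic", "other_substrate")
  out$substrate_class[has_pred] <- match_activity(out$activity[has_pred])
  out
}

#' Summarize lignocellulose classification
#'
#' Reports module totals per substrate class, the number of distinct
#' watchlist families observed, and the percentage of activity-predicted
#' modules that are lignocellulolytic / act on other substrates (one
#' decimal; `NA` when no module carries a prediction, never 0). Optionally
#' breaks counts down by metadata groups.
#'
#' @param annotated calls annotated by [classify_calls()].
#' @param meta optional sample metadata for grouping.
#' @param by optional character vector of metadata column names to group by
#'   (e.g. `"tissue"`, `"host_species"`).
#' @return list of class `"ligno_summary"`: `n_watchlist_modules`,
#'   `n_watchlist_families`, `n_predicted_modules`, `modules_by_class`
#'   (named vector), `pct_lignocellulolytic`, `pct_other_substrate`, and
#'   `by_group` (data.frame or `NULL`).
#' @export
summarize_classes <- function(annotated, meta = NULL, by = NULL) {
  w <- annotated[annotated$watchlist %in% TRUE, , drop = FALSE]
  mods <- function(idx) sum(w$module_count[idx])
  pred <- w$activity_source == "peptide_predictor"
  n_pred <- mods(pred)
  by_class <- vapply(c("lignocellulolytic", "other_substrate", "unresolved"),
                     function(cl) mods(w$substrate_class == cl), numeric(1L))
  pct <- function(cl) {
    if (n_pred == 0) return(NA_real_)
    round(100 * mods(pred & w$substrate_class == cl) / n_pred, 1L)
  }
  by_group <- NULL
  if (!is.null(by)) {
    stopifnot(!is.null(meta), all(by %in% names(meta)),
              "sample_id" %in% names(meta))
    g <- meta[match(w$sample_id, meta$sample_id), by, drop = FALSE]
    fam <- canonical_family(w$family, level = "family")
    key <- interaction(c(g, list(role = w$role)), drop = TRUE, sep = "\r")
    by_group <- do.call(rbind, lapply(levels(key), function(k) {
      idx <- key == k
      parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      d <- as.data.frame(as.list(parts), stringsAsFactors = FALSE)
      names(d) <- c(by, "role")
      d$n_families <- length(unique(fam[idx]))
      d$n_modules <- mods(idx)
      d
    }))
  }
  structure(list(
    n_watchlist_modules = mods(TRUE),
    n_watchlist_families = length(unique(canonical_family(w$family,
                                                          level = "family"))),
    n_predicted_modules = n_pred,
    modules_by_class = by_class,
    pct_lignocellulolytic = pct("lignocellulolytic"),
    pct_other_substrate = pct("other_substrate"),
    by_group = by_group
  ), class = "ligno_summary")
}

#' @export
print.ligno_summary <- function(x, ...) {
  cat(sprintf("Lignocellulose watchlist: %d families, %d modules\n",
              x$n_watchlist_families, x$n_watchlist_modules))
  cat(sprintf("  activity-predicted modules: %d\n", x$n_predicted_modules))
  cat(sprintf("  lignocellulolytic: %s%%   other substrates: %s%%\n",
              format(x$pct_lignocellulolytic),
              format(x$pct_other_substrate)))
  invisible(x)
}

#' Lignocellulose family richness ratio between host species
#'
#' Counts distinct watchlist families per host species among annotated
#' metagenome calls and returns each species' richness together with the
#' ratio of one focal species (e.g. an aquatic host) to the mean richness of
#' the others, rounded to one decimal.
#'
#' @param annotated calls annotated by [classify_calls()].
#' @param meta sample metadata (`sample_id`, `host_species`,
#'   `dataset_kind`).
#' @param focal_species the species whose richness goes in the numerator.
#' @return list with `richness` (named integer vector per species) and
#'   `ratio`.
#' @export
ligno_richness_ratio <- function(annotated, meta, focal_species) {
  w <- annotated[annotated$watchlist %in% TRUE, , drop = FALSE]
  mi <- match(w$sample_id, meta$sample_id)
  keep <- meta$dataset_kind[mi] == "metagenome"
  w <- w[keep, , drop = FALSE]
  sp <- meta$host_species[mi][keep]
  fam <- canonical_family(w$family, level = "family")
  richness <- vapply(split(fam, sp), function(f) length(unique(f)),
                     integer(1L))
  if (!focal_species %in% names(richness)) {
    stop("no metagenome watchlist calls for species: ", focal_species)
  }
  others <- richness[setdiff(names(richness), focal_species)]
  list(richness = richness,
       ratio = round(richness[[focal_species]] / mean(others), 1L))
}
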