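#' Readers and writers for the pipeline's plain-CSV formats
#'
#' All files are plain CSV with headers. The trait table is a taxon x
#' modality score matrix with a sidecar group map (`modality,group`); the
#' community matrix has sites in rows; the taxonomy is a 4-column table;
#' the pair table carries the treatment-plant covariates; EPT flags are a
#' 2-column table.
#'
#' @param dataset a `synthetic_dataset` (or a list with the same fields).
#' @param dir output directory (created if needed).
#' @return `write_dataset` invisibly returns the written paths;
#'   `read_dataset` the re-assembled list.
#' @name traitpair_io
NULL

#' @rdname traitpair_io
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write.csv(data.frame(taxon = rownames(dataset$traits$affinities),
                       dataset$traits$affinities, check.names = FALSE),
            p("traits.csv"), row.names = FALSE)
  write.csv(data.frame(modality = colnames(dataset$traits$affinities),
                       group = dataset$traits$groups),
            p("trait_groups.csv"), row.names = FALSE)
  write.csv(data.frame(site = rownames(dataset$comm), dataset$comm,
                       check.names = FALSE),
            p("community.csv"), row.names = FALSE)
  write.csv(as.data.frame(dataset$taxonomy), p("taxonomy.csv"), row.names = FALSE)
  write.csv(dataset$pairs, p("pairs.csv"), row.names = FALSE)
  write.csv(data.frame(taxon = names(dataset$ept), ept = dataset$ept),
            p("ept.csv"), row.names = FALSE)
  write.csv(dataset$sites, p("sites.csv"), row.names = FALSE)
  invisible(vapply(c("traits.csv", "trait_groups.csv", "community.csv",
                     "taxonomy.csv", "pairs.csv", "ept.csv", "sites.csv"),
                   p, character(1)))
}

#' @rdname traitpair_io
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  tr <- read.csv(p("traits.csv"), check.names = FALSE)
  gm <- read.csv(p("trait_groups.csv"))
  A <- as.matrix(tr[, -1, drop = FALSE])
  rownames(A) <- tr$taxon
  if (!identical(colnames(A), as.character(gm$modality)))
    stop("malformed trait header: modality columns do not match the group map")
  cm <- read.csv(p("community.csv"), check.names = FALSE)
  comm <- as.matrix(cm[, -1, drop = FALSE])
  rownames(comm) <- cm$site
  taxo <- read.csv(p("taxonomy.csv"), stringsAsFactors = FALSE)
  ept <- read.csv(p("ept.csv"), stringsAsFactors = FALSE)
  pairs <- read.csv(p("pairs.csv"), stringsAsFactors = FALSE)
  sites <- read.csv(p("sites.csv"), stringsAsFactors = FALSE)

  unknown <- setdiff(colnames(comm), union(rownames(A), taxo$taxon))
  if (length(unknown))
    stop("community taxa absent from traits and taxonomy: ",
         paste(unknown, collapse = ", "))
  empty <- rownames(comm)[rowSums(comm) == 0]
  if (length(empty)) {
    warning("excluding empty site rows: ", paste(empty, collapse = ", "),
            call. = FALSE)
    comm <- comm[rowSums(comm) > 0, , drop = FALSE]
  }
  list(traits = trait_table(A, as.character(gm$group)),
       comm = comm,
       taxonomy = taxonomy_table(taxo$taxon, taxo$genus, taxo$family, taxo$level),
       pairs = pairs,
       ept = setNames(ept$ept, ept$taxon),
       sites = sites)
}

#' Pipeline run configuration
#'
#' @param R null-model randomisations (default 999, minimum 99).
#' @param alpha significance level (default 0.05).
#' @param alpha_m_cap,beta_m_cap dimensionality caps for convex-hull
#'   metrics (default 3 and 3).
#' @param fric_standardize standardise FRic by the pool hull (default TRUE).
#' @param family beta dissimilarity family (`"jaccard"` or `"sorensen"`).
#' @param correction PCoA eigenvalue correction (`"sqrt"` or `"cailliez"`).
#' @param ept_threshold EPT-dominance threshold (default 0.5, inclusive).
#' @param seed run seed.
#' @param workers parallel workers over randomisations.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(R = 999, alpha = 0.05, alpha_m_cap = 3, beta_m_cap = 3,
                       fric_standardize = TRUE, family = "jaccard",
                       correction = "sqrt", ept_threshold = 0.5, seed = 1,
                       workers = 1) {
  if (R < 99) stop("R must be at least 99")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (ept_threshold < 0 || ept_threshold > 1) stop("ept_threshold in [0, 1]")
  structure(list(R = as.integer(R), alpha = alpha,
                 alpha_m_cap = alpha_m_cap, beta_m_cap = beta_m_cap,
                 fric_standardize = isTRUE(fric_standardize), family = family,
                 correction = correction, ept_threshold = ept_threshold,
                 seed = as.integer(seed), workers = as.integer(workers)),
            class = "run_config")
}

analyse_subset <- function(comm, pairs, traits_final, config, label) {
  taxa_here <- colnames(comm)[colSums(comm) > 0]
  sub_traits <- trait_table(traits_final$affinities[taxa_here, , drop = FALSE],
                            traits_final$groups, normalized = TRUE)
  sub_traits <- normalize_fuzzy(sub_traits)
  space <- build_functional_space(sub_traits, alpha_cap = config$alpha_m_cap,
                                  beta_cap = config$beta_m_cap,
                                  correction = config$correction)
  comm <- comm[, taxa_here, drop = FALSE]
  alpha_res <- alpha_diversity(comm, sub_traits, space,
                               fric_standardize = config$fric_standardize)
  beta_res <- beta_diversity(comm, pairs, space, family = config$family)
  nulls <- null_models(comm, sub_traits, space, alpha_res,
                       pairs = pairs, observed_beta = beta_res,
                       R = config$R, alpha = config$alpha, seed = config$seed,
                       workers = config$workers,
                       fric_standardize = config$fric_standardize,
                       family = config$family)
  # pair-aligned CWM matrices and tests
  cwm_up <- alpha_res$cwm[pairs$up_site, , drop = FALSE]
  cwm_dn <- alpha_res$cwm[pairs$down_site, , drop = FALSE]
  dcwm <- delta_cwm_tests(cwm_up, cwm_dn, alpha = config$alpha)
  # paired up/down tests on raw metrics and their SES, side by side
  met <- alpha_res$metrics
  ses_wide <- stats::reshape(nulls$alpha[, c("site", "metric", "ses")],
                             idvar = "site", timevar = "metric",
                             direction = "wide")
  names(ses_wide) <- sub("^ses\\.", "ses_", names(ses_wide))
  updown <- do.call(rbind, lapply(c("fric", "feve", "fdis", "rao", "redundancy"),
    function(m) {
      up <- met[[m]][match(pairs$up_site, met$site)]
      dn <- met[[m]][match(pairs$down_site, met$site)]
      raw <- tryCatch(paired_tests(up, dn), error = function(e) NULL)
      row <- data.frame(metric = m, kind = "raw",
                        statistic = raw$statistic %||% NA_real_,
                        p = raw$p %||% NA_real_, n_used = raw$n_used %||% 0L)
      sescol <- paste0("ses_", m)
      if (sescol %in% names(ses_wide)) {
        up_s <- ses_wide[[sescol]][match(pairs$up_site, ses_wide$site)]
        dn_s <- ses_wide[[sescol]][match(pairs$down_site, ses_wide$site)]
        ses <- tryCatch(paired_tests(up_s, dn_s), error = function(e) NULL)
        row <- rbind(row, data.frame(metric = m, kind = "ses",
                                     statistic = ses$statistic %||% NA_real_,
                                     p = ses$p %||% NA_real_,
                                     n_used = ses$n_used %||% 0L))
      }
      row
    }))
  cors <- covariate_correlations(nulls$beta, pairs)
  list(label = label, space = space, alpha = alpha_res, beta = beta_res,
       nulls = nulls, delta_cwm = dcwm, updown = updown, correlations = cors,
       sig_beta = significant_fraction(
         nulls$beta[nulls$beta$component == "beta_total", ]))
}

#' Run the full paired trait-based analysis pipeline
#'
#' Stage order: trait gap-filling and normalisation, community merging,
#' functional-space construction (Gower, PCoA, mSD dimensionality),
#' alpha and beta diversity, trait-shuffling null models with SES,
#' delta-CWM and paired Wilcoxon tests, covariate correlations, then the
#' EPT-dominated subset with a fully reconstructed functional space.
#' Deterministic given `config$seed` (and independent of `workers`).
#'
#' @param data list with `comm`, `traits` (raw `trait_table`), `taxonomy`,
#'   `pairs`, `ept` — e.g. a `synthetic_dataset` or [read_dataset()] output.
#' @param config a `run_config`.
#' @param outdir optional directory; when given, result CSVs and a JSON
#'   manifest are written.
#' @return list of class `pipeline_result`: `full` and `ept` analysis
#'   bundles (see source for fields), `coverage`, `config`.
#' @export
run_pipeline <- function(data, config = run_config(), outdir = NULL) {
  traits_n <- normalize_fuzzy(data$traits)
  gf <- fill_gaps(traits_n, data$taxonomy,
                  community_taxa = colnames(data$comm))
  comm <- merge_by_mapping(data$comm, gf$mapping)
  # EPT flag of a merged taxon: majority flag of its members
  ept_final <- vapply(colnames(comm), function(f) {
    mem <- gf$mapping$taxon[gf$mapping$final_taxon == f]
    mean(data$ept[mem]) >= 0.5
  }, logical(1))

  full <- analyse_subset(comm, data$pairs, gf$traits, config, "full")

  sub <- ept_subset(comm, data$pairs, ept_final, threshold = config$ept_threshold)
  ept_res <- NULL
  if (nrow(sub$pairs) >= 3) {
    ept_res <- analyse_subset(sub$comm, sub$pairs, gf$traits, config, "ept")
  }

  out <- structure(list(full = full, ept = ept_res, coverage = gf$coverage,
                        n_final_taxa = gf$n_final, dropped = gf$dropped,
                        ept_pairs = nrow(sub$pairs), config = config),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_results(out, outdir)
  out
}

#' Write a pipeline result bundle to CSV files plus a JSON manifest
#'
#' @param result a `pipeline_result`.
#' @param outdir output directory.
#' @return invisibly, the manifest path.
#' @export
write_results <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) write.csv(x, file.path(outdir, f), row.names = FALSE)
  for (lab in c("full", "ept")) {
    b <- result[[lab]]
    if (is.null(b)) next
    wr(b$alpha$metrics, paste0(lab, "_alpha_metrics.csv"))
    wr(data.frame(site = rownames(b$alpha$cwm), b$alpha$cwm,
                  check.names = FALSE), paste0(lab, "_cwm.csv"))
    wr(b$beta, paste0(lab, "_beta.csv"))
    wr(b$nulls$alpha, paste0(lab, "_null_alpha.csv"))
    wr(b$nulls$beta, paste0(lab, "_null_beta.csv"))
    wr(b$delta_cwm$tests, paste0(lab, "_delta_cwm_tests.csv"))
    wr(b$updown, paste0(lab, "_updown_tests.csv"))
    wr(b$correlations, paste0(lab, "_covariate_correlations.csv"))
  }
  wr(result$coverage, "trait_coverage.csv")
  manifest <- list(config = unclass(result$config),
                   n_final_taxa = result$n_final_taxa,
                   ept_pairs = result$ept_pairs,
                   version = as.character(utils::packageVersion("traitpair")))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
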