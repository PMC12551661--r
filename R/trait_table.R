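#' Construct a fuzzy-coded trait table
#'
#' A trait table holds taxon x modality affinity scores organised into trait
#' groups (e.g. feeding type, locomotion, reproduction). Fuzzy coding scores
#' each taxon's affinity to every modality of a group on a small
#' non-negative scale; [normalize_fuzzy()] converts the scores of each group
#' to relative frequencies summing to 1.
#'
#' @param affinities numeric matrix, taxa in rows (rownames required),
#'   modality columns (colnames required), non-negative.
#' @param groups character vector, one entry per modality column, naming the
#'   trait group the column belongs to. Columns of a group must be
#'   contiguous is not required, but each column belongs to exactly one
#'   group.
#' @param coding_level optional character vector per taxon recording the
#'   taxonomic level traits were coded at (`"original"`, `"subspecies"`,
#'   `"genus"`, `"family"`).
#' @param normalized logical, whether rows are already per-group relative
#'   frequencies.
#' @return an object of class `trait_table`: list with elements
#'   `affinities`, `groups`, `taxa`, `coding_level`, `normalized`.
#' @export
trait_table <- function(affinities, groups, coding_level = NULL, normalized = FALSE) {
  affinities <- as.matrix(affinities)
  if (is.null(rownames(affinities))) stop("trait table needs taxon rownames")
  if (is.null(colnames(affinities))) stop("trait table needs modality colnames")
  if (length(groups) != ncol(affinities))
    stop("`groups` must name a trait group per modality column")
  if (any(affinities < 0)) stop("negative trait affinity scores are not allowed")
  if (any(table(groups) < 2)) stop("every trait group needs >= 2 modalities")
  structure(
    list(affinities = affinities,
         groups = as.character(groups),
         taxa = rownames(affinities),
         coding_level = coding_level %||% rep("original", nrow(affinities)),
         normalized = isTRUE(normalized)),
    class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Fuzzy trait table:", length(x$taxa), "taxa,",
      length(unique(x$groups)), "trait groups,",
      ncol(x$affinities), "modalities;",
      if (x$normalized) "normalized\n" else "raw scores\n")
  invisible(x)
}

#' Column indices of each trait group
#' @param traits a `trait_table`
#' @return named list of integer column indices
#' @export
trait_group_index <- function(traits) {
  split(seq_along(traits$groups), traits$groups)[unique(traits$groups)]
}

#' Normalise fuzzy trait scores to per-group relative frequencies
#'
#' Within each trait group, a taxon's affinity scores are divided by their
#' sum so the group profile sums to 1. Groups in which a taxon scores zero
#' everywhere carry no information: they are left at zero and reported as
#' missing, never imputed.
#'
#' @param traits a `trait_table` with raw non-negative scores.
#' @return a normalised `trait_table` with an added `missing` logical matrix
#'   (taxa x groups) flagging all-zero groups.
#' @export
normalize_fuzzy <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  if (any(traits$affinities < 0)) stop("negative trait affinity scores are not allowed")
  A <- traits$affinities
  gidx <- trait_group_index(traits)
  miss <- matrix(FALSE, nrow(A), length(gidx),
                 dimnames = list(rownames(A), names(gidx)))
  for (g in names(gidx)) {
    cols <- gidx[[g]]
    s <- rowSums(A[, cols, drop = FALSE])
    zero <- s <= 0
    miss[, g] <- zero
    s[zero] <- 1
    A[, cols] <- A[, cols, drop = FALSE] / s
  }
  out <- traits
  out$affinities <- A
  out$normalized <- TRUE
  out$missing <- miss
  out
}

#' Construct a taxonomy table for trait gap-filling
#'
#' @param taxon character, taxon identifiers used in trait/community tables.
#' @param genus,family character vectors of the same length; `species` is
#'   taken to be the taxon id itself when coded at species level.
#' @param level character, taxonomic level of each record (`"species"`,
#'   `"genus"`, `"family"`).
#' @return a data.frame of class `taxonomy_table`.
#' @export
taxonomy_table <- function(taxon, genus, family, level) {
  stopifnot(length(taxon) == length(genus), length(genus) == length(family),
            length(level) == length(taxon))
  if (anyNA(family) || any(!nzchar(family)))
    stop("every taxon must resolve at least to family")
  out <- data.frame(taxon = as.character(taxon), genus = as.character(genus),
                    family = as.character(family), level = as.character(level),
                    stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Fill trait gaps by taxonomic aggregation
#'
#' Taxa without usable traits at their own level are raised to the next
#' highest taxonomic level (genus, then family) at which trait information
#' is available: the raised taxon receives, per trait group, the unweighted
#' mean of the normalised profiles of all coded pool members below that
#' parent, re-normalised. Community taxa sharing a raised parent are merged
#' into one final taxon (abundances summed by the caller via the returned
#' mapping). A parent is considered sufficiently covered for a group when it
#' has at least `min_donors` descendants coded in that group.
#'
#' @param traits a normalised `trait_table` over the taxon pool (with
#'   `missing` flags from [normalize_fuzzy()]).
#' @param taxonomy a `taxonomy_table` covering at least the community taxa.
#' @param community_taxa character, taxa that must end up with complete
#'   profiles.
#' @param min_donors minimum coded descendants per trait group for a parent
#'   to be usable (default 1).
#' @return list with elements:
#'   \describe{
#'     \item{traits}{`trait_table` over the final taxa (complete profiles)}
#'     \item{mapping}{data.frame `taxon` -> `final_taxon`, with the level
#'       traits were resolved at}
#'     \item{dropped}{character vector of taxa unresolvable even at family}
#'     \item{coverage}{data.frame of counts and percentages coded at each
#'       level among the retained community taxa}
#'   }
#' @export
fill_gaps <- function(traits, taxonomy, community_taxa, min_donors = 1L) {
  stopifnot(inherits(traits, "trait_table"), traits$normalized)
  if (is.null(traits$missing)) stop("run normalize_fuzzy() first")
  community_taxa <- sort(unique(as.character(community_taxa)))
  unknown <- setdiff(community_taxa, taxonomy$taxon)
  if (length(unknown))
    stop("community taxa missing from taxonomy: ", paste(unknown, collapse = ", "))

  gidx <- trait_group_index(traits)
  ngrp <- length(gidx)
  # a taxon is fully coded when no trait group is missing
  coded <- traits$taxa[rowSums(traits$missing) == 0]
  tax <- taxonomy[match(traits$taxa, taxonomy$taxon), ]

  group_mean_profile <- function(members) {
    # unweighted mean over descendants coded in each group, re-normalised
    prof <- numeric(ncol(traits$affinities))
    names(prof) <- colnames(traits$affinities)
    ok <- TRUE
    for (g in names(gidx)) {
      cols <- gidx[[g]]
      don <- members[!traits$missing[members, g]]
      if (length(don) < min_donors) { ok <- FALSE; break }
      m <- colMeans(traits$affinities[don, cols, drop = FALSE])
      s <- sum(m)
      prof[cols] <- if (s > 0) m / s else 0
      if (s <= 0) ok <- FALSE
    }
    if (ok) prof else NULL
  }

  map <- data.frame(taxon = community_taxa, final_taxon = NA_character_,
                    resolved_level = NA_character_, stringsAsFactors = FALSE)
  final_profiles <- list()
  dropped <- character(0)

  for (t in community_taxa) {
    i <- match(t, traits$taxa)
    rec <- taxonomy[match(t, taxonomy$taxon), ]
    if (!is.na(i) && t %in% coded) {
      map$final_taxon[map$taxon == t] <- t
      map$resolved_level[map$taxon == t] <- traits$coding_level[i]
      final_profiles[[t]] <- traits$affinities[i, ]
      next
    }
    placed <- FALSE
    for (lev in c("genus", "family")) {
      parent <- rec[[lev]]
      if (is.na(parent) || !nzchar(parent)) next
      members <- which(!is.na(tax[[lev]]) & tax[[lev]] == parent)
      if (!length(members)) next
      prof <- group_mean_profile(members)
      if (is.null(prof)) next
      fid <- paste0(parent, " (", lev, ")")
      if (is.null(final_profiles[[fid]])) final_profiles[[fid]] <- prof
      map$final_taxon[map$taxon == t] <- fid
      map$resolved_level[map$taxon == t] <- lev
      placed <- TRUE
      break
    }
    if (!placed) {
      dropped <- c(dropped, t)
      warning("taxon '", t, "' has no usable traits even at family level; dropped",
              call. = FALSE)
    }
  }

  kept <- map[!is.na(map$final_taxon), ]
  prof_mat <- do.call(rbind, final_profiles[unique(kept$final_taxon)])
  out_traits <- trait_table(prof_mat, traits$groups,
                            coding_level = vapply(unique(kept$final_taxon), function(f) {
                              lv <- kept$resolved_level[kept$final_taxon == f][1]
                              if (lv %in% c("genus", "family")) lv else lv
                            }, character(1)),
                            normalized = TRUE)
  out_traits <- normalize_fuzzy(out_traits)  # refresh missing flags (none expected)

  lvls <- c("original", "subspecies", "genus", "family")
  cov_counts <- table(factor(kept$resolved_level,
                             levels = union(lvls, unique(kept$resolved_level))))
  coverage <- data.frame(level = names(cov_counts),
                         n = as.integer(cov_counts),
                         pct = 100 * as.integer(cov_counts) / nrow(kept))

  list(traits = out_traits, mapping = kept, dropped = dropped,
       coverage = coverage, n_final = length(unique(kept$final_taxon)))
}

#' Merge community abundances according to a gap-filling mapping
#'
#' Community taxa resolved to the same final (possibly raised) taxon are
#' merged by summing their abundances; total abundance per site is
#' conserved for retained taxa.
#'
#' @param comm site x taxon abundance matrix.
#' @param mapping data.frame `taxon` -> `final_taxon` from [fill_gaps()].
#' @return site x final-taxon abundance matrix.
#' @export
merge_by_mapping <- function(comm, mapping) {
  comm <- as.matrix(comm)
  keep <- intersect(colnames(comm), mapping$taxon)
  comm <- comm[, keep, drop = FALSE]
  fin <- mapping$final_taxon[match(keep, mapping$taxon)]
  out <- t(rowsum(t(comm), group = fin))
  out[, sort(unique(fin)), drop = FALSE]
}

#' Proportion of EPT individuals in a community
#'
#' Ephemeroptera, Plecoptera and Trichoptera (EPT) are pollution-sensitive
#' insect orders; a community is EPT-dominated when at least half of its
#' individuals belong to them (boundary inclusive).
#'
#' @param abundance non-negative abundance vector (named by taxon or aligned
#'   with `ept_flags`).
#' @param ept_flags logical vector flagging EPT taxa.
#' @return proportion in \[0, 1\].
#' @export
ept_proportion <- function(abundance, ept_flags) {
  if (!is.null(names(abundance)) && !is.null(names(ept_flags)))
    ept_flags <- ept_flags[names(abundance)]
  stopifnot(length(abundance) == length(ept_flags))
  if (any(abundance < 0)) stop("negative abundances")
  tot <- sum(abundance)
  if (tot <= 0) stop("empty community: EPT proportion undefined")
  sum(abundance[ept_flags]) / tot
}
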