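#' Relationship thresholds for pedigree reconstruction
#'
#' @param parent_offspring_min minimum realized relationship to accept a
#'   parent-offspring link (default 0.15).
#' @param halfsib_min minimum offspring-offspring relationship counted as
#'   half-sib cohesion (default 0.07).
#' @param duplicate_min relationship above which two samples are called the
#'   same tree genotyped twice (default 0.80).
#' @param self_parent_min parent relationship above which an offspring with
#'   no distinct qualifying father is called a self (default 0.70).
#' @param split_min_group minimum subgroup size to declare a dual-genotype
#'   family split (default 5).
#' @return object of class `px_thresholds`.
#' @export
threshold_config <- function(parent_offspring_min = 0.15, halfsib_min = 0.07,
                             duplicate_min = 0.80, self_parent_min = 0.70,
                             split_min_group = 5L) {
  if (!(0 < halfsib_min && halfsib_min < parent_offspring_min &&
        parent_offspring_min < self_parent_min &&
        self_parent_min < duplicate_min && duplicate_min <= 2))
    stop("thresholds must satisfy 0 < halfsib < parent-offspring < self < duplicate <= 2")
  structure(list(parent_offspring_min = parent_offspring_min,
                 halfsib_min = halfsib_min, duplicate_min = duplicate_min,
                 self_parent_min = self_parent_min,
                 split_min_group = as.integer(split_min_group)),
            class = "px_thresholds")
}

## argmax with deterministic lowest-id tie-break; warns when a tie occurs
argmax_id <- function(values, ids) {
  mx <- max(values)
  cand <- ids[values >= mx - 1e-12]
  if (length(cand) > 1L) {
    warning("tied maximal relationship; choosing lowest-sorting id",
            call. = FALSE)
    cand <- sort(cand)
  }
  list(id = cand[1L], value = mx)
}

#' Verify recorded maternity against the realized relationship matrix
#'
#' For each offspring the candidate mother is the genotyped female with the
#' maximal realized relationship; the call is confirmed when that maximum
#' reaches the parent-offspring threshold, and flagged as a pedigree error
#' when it disagrees with the recorded mother.
#'
#' @param G realized relationship matrix covering offspring and genotyped
#'   females.
#' @param recorded recorded pedigree (`id`, `mother`).
#' @param female_ids genotyped candidate mothers.
#' @param th a [threshold_config()].
#' @return data.frame with `offspring_id`, `recorded_mother`,
#'   `confirmed_mother` (NA when unassigned), `mother_relationship`,
#'   `pedigree_error` flag.
#' @export
verify_maternity <- function(G, recorded, female_ids, th = threshold_config()) {
  off <- as.character(recorded$id)
  if (!all(off %in% rownames(G)))
    stop("offspring missing from relationship matrix")
  female_ids <- intersect(female_ids, rownames(G))
  if (length(female_ids) == 0L) stop("no genotyped females in G")
  sub <- unclass(G)[off, female_ids, drop = FALSE]
  out <- data.frame(offspring_id = off,
                    recorded_mother = as.character(recorded$mother),
                    confirmed_mother = NA_character_,
                    mother_relationship = NA_real_,
                    pedigree_error = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(off)) {
    am <- argmax_id(sub[i, ], female_ids)
    out$mother_relationship[i] <- am$value
    if (am$value >= th$parent_offspring_min) {
      out$confirmed_mother[i] <- am$id
      out$pedigree_error[i] <- !identical(am$id, out$recorded_mother[i])
    }
  }
  out
}

#' Detect a dual-genotype (split) maternal family
#'
#' Partitions a recorded maternal family by relationship to the genotyped
#' mother. A split is declared only when both groups reach the minimum size,
#' the group unrelated to the genotyped mother is internally cohesive at the
#' half-sib level (mean within-group relationship at or above the half-sib
#' threshold and at most 20% of its pairs below it, i.e. the within-group
#' histogram loses its peak at zero relationship), confirming a shared hidden
#' mother. The hidden group's mother is relabeled `<mother>_B`.
#'
#' @param G realized relationship matrix.
#' @param offspring_ids members of the recorded family.
#' @param mother_id genotyped mother id (must appear in `G`).
#' @param th a [threshold_config()].
#' @return list `is_split`, `group_A` (related to the genotyped mother),
#'   `group_B`, `hidden_mother_label`.
#' @export
detect_family_split <- function(G, offspring_ids, mother_id,
                                th = threshold_config()) {
  if (!(mother_id %in% rownames(G)))
    stop("mother not genotyped; no split attempted")
  offspring_ids <- intersect(offspring_ids, rownames(G))
  relm <- unclass(G)[offspring_ids, mother_id]
  grp_a <- offspring_ids[relm >= th$parent_offspring_min]
  grp_b <- setdiff(offspring_ids, grp_a)
  res <- list(is_split = FALSE, group_A = grp_a, group_B = character(0),
              hidden_mother_label = NA_character_)
  if (length(offspring_ids) < 2L * th$split_min_group) return(res)
  if (length(grp_a) < th$split_min_group || length(grp_b) < th$split_min_group)
    return(res)
  bb <- unclass(G)[grp_b, grp_b]
  pairs <- bb[upper.tri(bb)]
  if (mean(pairs) >= th$halfsib_min && mean(pairs < th$halfsib_min) <= 0.2) {
    res$is_split <- TRUE
    res$group_B <- grp_b
    res$hidden_mother_label <- paste0(mother_id, "_B")
  }
  res
}

#' Assign paternity from the realized relationship matrix
#'
#' The father is the candidate male with the maximal relationship, accepted
#' at the parent-offspring threshold; otherwise the offspring is classed a
#' contaminant (foreign pollen). A confirmation pass then demotes offspring
#' whose mean relationship to their assembled paternal half-sib family falls
#' below the half-sib threshold. Offspring whose relationship to their
#' confirmed mother exceeds the selfing threshold and that lack a distinct
#' qualifying father are classed as selfs.
#'
#' @param G realized relationship matrix.
#' @param maternity output of [verify_maternity()].
#' @param male_ids candidate pollen donors present in `G`.
#' @param th a [threshold_config()].
#' @return data.frame `offspring_id`, `assigned_father`,
#'   `father_relationship`, `status` in
#'   `assigned`/`mother_unassigned`/`contaminant`/`self`.
#' @export
assign_paternity <- function(G, maternity, male_ids, th = threshold_config()) {
  if (length(male_ids) == 0L) stop("empty candidate male list")
  male_ids <- intersect(male_ids, rownames(G))
  off <- maternity$offspring_id
  sub <- unclass(G)[off, male_ids, drop = FALSE]
  out <- data.frame(offspring_id = off, assigned_father = NA_character_,
                    father_relationship = NA_real_, status = "contaminant",
                    stringsAsFactors = FALSE)
  for (i in seq_along(off)) {
    am <- argmax_id(sub[i, ], male_ids)
    out$father_relationship[i] <- am$value
    mother <- maternity$confirmed_mother[i]
    mother_rel <- maternity$mother_relationship[i]
    ## self: near-total relationship to the mother and no distinct father
    is_self <- !is.na(mother) && mother_rel >= th$self_parent_min &&
      (am$value < th$parent_offspring_min || identical(am$id, mother))
    if (is_self) {
      out$status[i] <- "self"
    } else if (am$value >= th$parent_offspring_min) {
      out$assigned_father[i] <- am$id
      out$status[i] <- "assigned"
    }
    if (is.na(mother) && out$status[i] != "self")
      out$status[i] <- "mother_unassigned"
  }
  ## confirmation pass within assembled paternal half-sib families
  assigned <- which(out$status == "assigned")
  fam <- split(assigned, out$assigned_father[assigned])
  for (members in fam) {
    if (length(members) < 2L) next
    ids <- out$offspring_id[members]
    bb <- unclass(G)[ids, ids]
    mean_rel <- (rowSums(bb) - diag(bb)) / (length(ids) - 1L)
    bad <- members[mean_rel < th$halfsib_min]
    if (length(bad)) {
      out$status[bad] <- "contaminant"
      out$assigned_father[bad] <- NA_character_
    }
  }
  out
}

#' Detect duplicate genotyped samples
#'
#' Reports all unordered pairs with relationship at or above the duplicate
#' threshold; within each pair the member with more missing genotype calls is
#' flagged for removal.
#'
#' @param G realized relationship matrix (offspring rows/cols considered).
#' @param th a [threshold_config()].
#' @param missing_counts optional named vector of per-individual missing-call
#'   counts used to pick the member to drop (defaults to zero).
#' @return data.frame `id1`, `id2`, `relationship`, `remove`.
#' @export
detect_duplicates <- function(G, th = threshold_config(),
                              missing_counts = NULL) {
  ids <- rownames(G)
  out <- data.frame(id1 = character(0), id2 = character(0),
                    relationship = numeric(0), remove = character(0),
                    stringsAsFactors = FALSE)
  if (length(ids) < 2L) return(out)
  m <- unclass(G)
  hits <- which(upper.tri(m) & m >= th$duplicate_min, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(out)
  mc <- function(id) {
    if (is.null(missing_counts) || !(id %in% names(missing_counts))) 0
    else missing_counts[[id]]
  }
  for (r in seq_len(nrow(hits))) {
    i1 <- ids[hits[r, 1]]; i2 <- ids[hits[r, 2]]
    drop_id <- if (mc(i2) > mc(i1)) i2 else i1
    out <- rbind(out, data.frame(id1 = i1, id2 = i2,
                                 relationship = m[hits[r, 1], hits[r, 2]],
                                 remove = drop_id, stringsAsFactors = FALSE))
  }
  out
}

#' Chi-squared test of equal male contribution
#'
#' Tests the realized paternal counts (contaminants and selfs excluded)
#' against the equal-contribution expectation total/k.
#'
#' @param counts_per_male named or unnamed integer vector of offspring counts
#'   per pollen donor.
#' @return list with `counts_per_male`, `expected_count`, `chi2`, `df`,
#'   `p_value`.
#' @examples
#' test_equal_contribution(c(20, 10))$chi2  # (20-15)^2/15 + (10-15)^2/15
#' @export
test_equal_contribution <- function(counts_per_male) {
  total <- sum(counts_per_male)
  if (total == 0) stop("no assigned offspring: contribution test undefined")
  k <- length(counts_per_male)
  expected <- total / k
  chi2 <- sum((counts_per_male - expected)^2 / expected)
  df <- k - 1L
  list(counts_per_male = counts_per_male, expected_count = expected,
       chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Build the reconstructed full-sib pedigree
#'
#' Combines maternity and paternity calls into a corrected pedigree:
#' assigned offspring get both parents, contaminants keep their confirmed
#' mother with an unknown father, selfs get mother = father, and hidden
#' mothers from family splits enter as new founders.
#'
#' @param maternity output of [verify_maternity()] (after split relabeling).
#' @param paternity output of [assign_paternity()].
#' @param drop_ids ids to exclude (e.g. duplicate removals).
#' @return list with `pedigree` (founders first, then offspring) and
#'   `family_summary` (`n_fs_families`, `fs_family_sizes`).
#' @export
build_fs_pedigree <- function(maternity, paternity, drop_ids = character(0)) {
  stopifnot(identical(maternity$offspring_id, paternity$offspring_id))
  keep <- !(maternity$offspring_id %in% drop_ids)
  mat <- maternity[keep, ]; pat <- paternity[keep, ]
  mother <- mat$confirmed_mother
  father <- pat$assigned_father
  father[pat$status == "self"] <- mother[pat$status == "self"]
  founders <- sort(unique(stats::na.omit(c(mother, father))))
  ped <- rbind(
    data.frame(id = founders, mother = NA_character_, father = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = mat$offspring_id, mother = mother, father = father,
               stringsAsFactors = FALSE))
  both <- !is.na(mother) & !is.na(father)
  fs <- table(paste(mother[both], father[both], sep = "x"))
  list(pedigree = ped,
       family_summary = list(n_fs_families = length(fs),
                             fs_family_sizes = as.integer(fs)))
}

#' Full relationship-based pedigree reconstruction
#'
#' Runs the reconstruction stages in order: duplicate detection, maternity
#' verification, dual-genotype family-split detection, paternity assignment
#' with half-sib confirmation and self detection, the equal-contribution
#' chi-squared test, and full-sib pedigree assembly.
#'
#' @param G realized additive relationship matrix over parents + offspring.
#' @param recorded recorded pedigree (`id`, `mother`) for offspring.
#' @param female_ids,male_ids genotyped candidate parents.
#' @param th a [threshold_config()].
#' @param missing_counts optional per-individual missing-call counts.
#' @return list with `duplicates`, `maternity`, `splits`, `paternity`,
#'   `contribution_test`, `pedigree`, `family_summary`, `status` (one call
#'   per offspring).
#' @export
reconstruct_pedigree <- function(G, recorded, female_ids, male_ids,
                                 th = threshold_config(),
                                 missing_counts = NULL) {
  off_ids <- as.character(recorded$id)
  dup <- detect_duplicates(G[off_ids, off_ids], th, missing_counts)
  drop_ids <- unique(dup$remove)
  recorded <- recorded[!(recorded$id %in% drop_ids), , drop = FALSE]

  mat <- verify_maternity(G, recorded, female_ids, th)

  ## family splits among recorded families with genotyped mothers
  splits <- list()
  for (fm in unique(mat$recorded_mother)) {
    if (!(fm %in% rownames(G))) next
    ## candidates: recorded under this mother and not already confirmed to a
    ## different genotyped female (maternal mislabels are resolved upstream)
    fam_ids <- mat$offspring_id[mat$recorded_mother == fm &
                                  (is.na(mat$confirmed_mother) |
                                     mat$confirmed_mother == fm)]
    sp <- detect_family_split(G, fam_ids, fm, th)
    if (sp$is_split) {
      splits[[fm]] <- sp
      idx <- mat$offspring_id %in% sp$group_B & is.na(mat$confirmed_mother)
      mat$confirmed_mother[idx] <- sp$hidden_mother_label
    }
  }

  pat <- assign_paternity(G, mat, male_ids, th)
  dup_status <- stats::setNames(rep("duplicate", length(drop_ids)), drop_ids)
  status <- c(stats::setNames(pat$status, pat$offspring_id), dup_status)

  assigned <- pat$status == "assigned"
  counts <- table(factor(pat$assigned_father[assigned], levels = sort(male_ids)))
  ct <- test_equal_contribution(as.integer(counts))

  fs <- build_fs_pedigree(mat, pat)
  list(duplicates = dup, maternity = mat, splits = splits, paternity = pat,
       contribution_test = ct, pedigree = fs$pedigree,
       family_summary = fs$family_summary, status = status[off_ids[off_ids %in% names(status)]])
}
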