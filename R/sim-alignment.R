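#' Configuration for simulating a two-haplogroup alignment
#'
#' Describes a synthetic phased alignment of the FADS-style haplogroup region:
#' two deeply diverged modern clusters (derived and ancestral) plus archaic
#' lineages branching at intermediate times, evolved from a reconstructed
#' human-chimp ancestor sequence under the infinite-sites model. Mutations are
#' Poisson along each lineage with per-site yearly rate `a_hc / (2 * t_hc)`
#' and are placed on distinct high-quality sites, so a divergence-based TMRCA
#' estimator applied to the output has known truth.
#'
#' @param n_derived,n_ancestral Number of haplotypes in the derived and
#'   ancestral clusters.
#' @param n_archaic_near_derived,n_archaic_near_ancestral Number of archaic
#'   haplotypes branching near the derived / ancestral stems.
#' @param length_total Total region length in bases (default 48,408).
#' @param length_high_quality Number of sites with a usable ancestor
#'   reconstruction (default 47,820); mutations are only placed here.
#' @param tmrca_derived True age (years) of the derived cluster; each derived
#'   lineage accumulates mutations over this time.
#' @param tmrca_all True root age (years) of both clusters; ancestral lineages
#'   accumulate mutations over this time.
#' @param archaic_branch_time Age (years) of the archaic branches
#'   (default 650,000).
#' @param a_hc Human-chimp per-site divergence fraction (default 0.00829).
#' @param t_hc Human-chimp divergence time in years (default 6,500,000).
#' @param genealogy Genealogy of the *derived* cluster. `"star"` (default):
#'   independent Poisson lineages, the model under which the mean divergence
#'   estimator's target is exactly `tmrca_derived`; or `"coalescent"`: a
#'   Kingman tree rescaled to the cluster age, under which lineages share
#'   internal branches. The ancestral cluster always uses a coalescent
#'   genealogy (a population sample shares most of its variation; independent
#'   star lineages of age `tmrca_all` would be unrealistically diverse and
#'   flood the infinite-sites filter).
#' @param stem_mutations_derived,stem_mutations_ancestral Number of mutations
#'   fixed across the whole cluster (planted on the cluster stem). Zero by
#'   default; used to create cluster-diagnostic fixed differences.
#' @param plant_tag_snp If `TRUE`, add the rs174537-style tag SNP at
#'   chr11:61,552,680 with the ancestor/ancestral clusters carrying T and all
#'   derived haplotypes carrying G.
#' @param chrom,region_start Coordinates of the simulated region.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `haplogroup_sim_config`.
#' @export
haplogroup_sim_config <- function(n_derived = 50, n_ancestral = 50,
                                  n_archaic_near_derived = 2,
                                  n_archaic_near_ancestral = 2,
                                  length_total = 48408,
                                  length_high_quality = 47820,
                                  tmrca_derived = 688474,
                                  tmrca_all = 1490000,
                                  archaic_branch_time = 650000,
                                  a_hc = 0.00829, t_hc = 6.5e6,
                                  genealogy = c("star", "coalescent"),
                                  stem_mutations_derived = 0,
                                  stem_mutations_ancestral = 0,
                                  plant_tag_snp = FALSE,
                                  chrom = "chr11", region_start = 61543499,
                                  seed = 1L) {
  genealogy <- match.arg(genealogy)
  for (nm in c("n_derived", "n_ancestral", "n_archaic_near_derived",
               "n_archaic_near_ancestral", "stem_mutations_derived",
               "stem_mutations_ancestral")) {
    assert_count(get(nm), nm)
  }
  length_total <- assert_count(length_total, "length_total", min = 1)
  length_high_quality <- assert_count(length_high_quality, "length_high_quality", min = 1)
  if (length_high_quality > length_total) {
    abort("`length_high_quality` must not exceed `length_total`.")
  }
  if (!(tmrca_derived >= 0 && tmrca_all > 0 && tmrca_derived <= tmrca_all)) {
    abort("Need 0 <= tmrca_derived <= tmrca_all and tmrca_all > 0.")
  }
  if (!(a_hc > 0 && a_hc < 1)) abort("`a_hc` must lie in (0, 1).")
  if (t_hc <= 0) abort("`t_hc` must be positive.")
  structure(
    list(n_derived = n_derived, n_ancestral = n_ancestral,
         n_archaic_near_derived = n_archaic_near_derived,
         n_archaic_near_ancestral = n_archaic_near_ancestral,
         length_total = length_total,
         length_high_quality = length_high_quality,
         tmrca_derived = tmrca_derived, tmrca_all = tmrca_all,
         archaic_branch_time = archaic_branch_time,
         a_hc = a_hc, t_hc = t_hc, genealogy = genealogy,
         stem_mutations_derived = stem_mutations_derived,
         stem_mutations_ancestral = stem_mutations_ancestral,
         plant_tag_snp = isTRUE(plant_tag_snp),
         chrom = chrom, region_start = as.integer(region_start),
         seed = as.integer(seed)),
    class = "haplogroup_sim_config")
}

# Per-haplotype numbers of mutation events per lineage segment.
# Returns a list: one integer vector of event counts per haplotype for
# star genealogies, or a list(edge_counts, membership) for coalescent trees.
cluster_event_sets <- function(n, age_years, rate_site_year, n_sites, genealogy) {
  mean_per_lineage <- age_years * rate_site_year * n_sites
  if (n == 0) return(list())
  if (genealogy == "star" || n < 3) {
    counts <- rpois(n, mean_per_lineage)
    return(lapply(counts, function(k) rep(0L, k))) # placeholder slots, sites later
  }
  # Kingman topology rescaled so the root depth equals age_years.
  tr <- ape::rcoal(n)
  depths <- ape::node.depth.edgelength(tr)
  root_depth <- max(depths[seq_len(n)])
  tr$edge.length <- tr$edge.length * (age_years / root_depth)
  edge_events <- rpois(nrow(tr$edge), tr$edge.length * rate_site_year * n_sites)
  # haplotype i inherits the events on every edge above it
  tips_below <- function(node) {
    if (node <= n) return(node)
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  desc <- lapply(tr$edge[, 2], tips_below)
  per_hap <- vector("list", n)
  ev_id <- 0L
  for (e in seq_along(edge_events)) {
    k <- edge_events[e]
    if (k == 0) next
    ids <- ev_id + seq_len(k)
    ev_id <- ev_id + k
    for (tip in desc[[e]]) per_hap[[tip]] <- c(per_hap[[tip]], ids)
  }
  lapply(per_hap, function(x) x %||% integer(0))
}

#' Simulate a two-haplogroup phased alignment with known TMRCA
#'
#' Generates a random ancestor sequence over the region, then evolves derived,
#' ancestral and archaic haplotypes under the infinite-sites model: every
#' mutation event lands on its own high-quality site, as a random base
#' different from the ancestor's. Under the default star genealogy each
#' derived lineage carries `Poisson(tmrca_derived * a_hc/(2 t_hc) * L_hq)`
#' private mutations (about 21 at the defaults).
#'
#' @param config A [haplogroup_sim_config()].
#' @return A `hap_alignment` object: variant matrix (haplotypes x variant
#'   sites), variant positions, full-length ancestor sequence, high-quality
#'   mask, and a metadata tibble with per-haplotype cluster labels.
#' @examples
#' aln <- simulate_haplogroup_alignment(
#'   haplogroup_sim_config(n_derived = 5, n_ancestral = 5, seed = 42))
#' aln
#' @export
simulate_haplogroup_alignment <- function(config) {
  stopifnot(inherits(config, "haplogroup_sim_config"))
  withr::local_seed(config$seed)
  cfg <- config
  rate <- cfg$a_hc / (2 * cfg$t_hc) # per site per year, per lineage

  hq_mask <- rep(FALSE, cfg$length_total)
  hq_mask[sample.int(cfg$length_total, cfg$length_high_quality)] <- TRUE
  ancestor_full <- random_bases(cfg$length_total)

  tag <- fads_tag_snp()
  tag_offset <- tag$pos - cfg$region_start + 1L
  if (cfg$plant_tag_snp) {
    if (tag_offset < 1 || tag_offset > cfg$length_total) {
      abort("Tag SNP position falls outside the simulated region.")
    }
    ancestor_full[tag_offset] <- tag$ancestral_allele
    hq_mask[tag_offset] <- TRUE
  }

  groups <- list(
    derived = list(n = cfg$n_derived, age = cfg$tmrca_derived),
    ancestral = list(n = cfg$n_ancestral, age = cfg$tmrca_all),
    archaic_near_derived = list(n = cfg$n_archaic_near_derived,
                                age = cfg$archaic_branch_time),
    archaic_near_ancestral = list(n = cfg$n_archaic_near_ancestral,
                                  age = cfg$archaic_branch_time))

  # Private/lineage events per haplotype (shared ids under the coalescent).
  events <- list(); meta <- list(); next_id <- 0L
  for (g in names(groups)) {
    gi <- groups[[g]]
    if (gi$n == 0) next
    # `genealogy` governs the derived cluster only: star there makes the
    # per-haplotype divergences i.i.d., the geometry under which the TMRCA
    # estimator's target is exactly `tmrca_derived`. The ancestral cluster
    # is a population sample, so its lineages always share a coalescent
    # genealogy -- independent star lineages of age `tmrca_all` would carry
    # vastly more intra-cluster diversity than any real population and
    # saturate the infinite-sites filter with spurious exclusions.
    geneal <- if (g == "derived") cfg$genealogy
              else if (g == "ancestral") "coalescent" else "star"
    sets <- cluster_event_sets(gi$n, gi$age, rate, cfg$length_high_quality, geneal)
    raw_max <- max(c(0L, unlist(sets)))
    if (geneal == "star" || gi$n < 3) {
      # star placeholders are zero-filled slots; assign fresh global ids
      sets <- lapply(sets, function(x) {
        if (!length(x)) return(integer(0))
        ids <- next_id + seq_along(x); next_id <<- next_id + length(x); ids
      })
    } else {
      sets <- lapply(sets, function(x) if (length(x)) next_id + x else integer(0))
      next_id <- next_id + raw_max
    }
    events <- c(events, setNames(sets, sprintf("%s_%02d", g, seq_len(gi$n))))
    meta[[g]] <- tibble(haplotype = sprintf("%s_%02d", g, seq_len(gi$n)),
                        cluster = g)
  }
  meta <- bind_rows(meta)

  # Stem (cluster-fixed) events.
  stem_der <- if (cfg$stem_mutations_derived > 0)
    max(unlist(c(0L, events))) + seq_len(cfg$stem_mutations_derived) else integer(0)
  stem_anc <- if (cfg$stem_mutations_ancestral > 0)
    max(unlist(c(0L, events, stem_der))) + seq_len(cfg$stem_mutations_ancestral) else integer(0)
  for (h in names(events)) {
    cl <- meta$cluster[match(h, meta$haplotype)]
    if (cl %in% c("derived", "archaic_near_derived")) events[[h]] <- c(events[[h]], stem_der)
    if (cl %in% c("ancestral", "archaic_near_ancestral")) events[[h]] <- c(events[[h]], stem_anc)
  }

  all_ids <- sort(unique(unlist(events)))
  hq_offsets <- which(hq_mask)
  if (cfg$plant_tag_snp) hq_offsets <- setdiff(hq_offsets, tag_offset)
  if (length(all_ids) > length(hq_offsets)) {
    abort(sprintf(
      "Mutation budget (%d events) exceeds the %d available high-quality sites; infinite-sites model cannot hold.",
      length(all_ids), length(hq_offsets)))
  }
  site_of_event <- sample(hq_offsets, length(all_ids))
  names(site_of_event) <- as.character(all_ids)

  var_offsets <- sort(unique(c(site_of_event,
                               if (cfg$plant_tag_snp) tag_offset)))
  if (length(var_offsets) == 0) {
    var_offsets <- integer(0)
  }
  anc_var <- ancestor_full[var_offsets]
  alt_var <- mutate_base(anc_var)

  n_hap <- nrow(meta)
  mat <- matrix(rep(anc_var, each = n_hap), nrow = n_hap,
                dimnames = list(meta$haplotype,
                                as.character(cfg$region_start + var_offsets - 1L)))
  col_of_offset <- setNames(seq_along(var_offsets), var_offsets)
  for (h in names(events)) {
    offs <- site_of_event[as.character(events[[h]])]
    if (length(offs)) {
      cols <- col_of_offset[as.character(offs)]
      mat[h, cols] <- alt_var[cols]
    }
  }
  if (cfg$plant_tag_snp) {
    tcol <- col_of_offset[as.character(tag_offset)]
    alt_var[tcol] <- tag$derived_allele
    mat[, tcol] <- tag$ancestral_allele
    mat[meta$haplotype[meta$cluster == "derived"], tcol] <- tag$derived_allele
  }

  new_hap_alignment(
    haplotypes = mat,
    pos = as.integer(cfg$region_start + var_offsets - 1L),
    chrom = cfg$chrom,
    ancestor_full = ancestor_full,
    region_start = cfg$region_start,
    hq_mask = hq_mask,
    meta = meta,
    truth = list(tmrca_derived = cfg$tmrca_derived, tmrca_all = cfg$tmrca_all,
                 a_hc = cfg$a_hc, t_hc = cfg$t_hc, genealogy = cfg$genealogy))
}

#' Construct a phased haplotype alignment
#'
#' Low-level constructor for the container used throughout the package: a
#' character matrix of haplotypes over variant sites, their 1-based genomic
#' positions, the full-length reconstructed ancestor sequence, a per-site
#' high-quality mask, and a metadata tibble with one row per haplotype
#' (`haplotype` id and `cluster` label at minimum).
#'
#' @param haplotypes Character matrix, haplotypes x variant sites; rownames
#'   are haplotype ids.
#' @param pos Integer vector of variant positions (one per column).
#' @param chrom Chromosome name.
#' @param ancestor_full Character vector: ancestor base at every site of the
#'   region (its length defines the region length).
#' @param region_start 1-based genomic coordinate of the region's first site.
#' @param hq_mask Logical vector over the whole region marking high-quality
#'   ancestor sites; defaults to all `TRUE`.
#' @param meta Tibble with columns `haplotype`, `cluster`; defaults to the
#'   matrix rownames with no cluster labels.
#' @return A `hap_alignment` object.
#' @export
hap_alignment <- function(haplotypes, pos, chrom = "chr11", ancestor_full,
                          region_start = 1L,
                          hq_mask = rep(TRUE, length(ancestor_full)),
                          meta = NULL) {
  if (is.null(rownames(haplotypes))) {
    rownames(haplotypes) <- sprintf("hap%03d", seq_len(nrow(haplotypes)))
  }
  meta <- meta %||% tibble(haplotype = rownames(haplotypes),
                           cluster = NA_character_)
  new_hap_alignment(haplotypes, pos, chrom, ancestor_full, region_start,
                    hq_mask, meta)
}

new_hap_alignment <- function(haplotypes, pos, chrom, ancestor_full,
                              region_start, hq_mask, meta, truth = NULL) {
  stopifnot(is.matrix(haplotypes), length(pos) == ncol(haplotypes),
            length(hq_mask) >= 1, nrow(meta) == nrow(haplotypes))
  structure(list(haplotypes = haplotypes, pos = as.integer(pos), chrom = chrom,
                 ancestor_full = ancestor_full,
                 region_start = as.integer(region_start),
                 hq_mask = hq_mask, meta = meta, truth = truth),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %d haplotypes x %d variant sites (%s:%d-%d)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$chrom, x$region_start,
              x$region_start + length(x$hq_mask) - 1L))
  cat(sprintf("  high-quality sites: %d / %d\n", sum(x$hq_mask), length(x$hq_mask)))
  tab <- table(x$meta$cluster)
  cat("  clusters:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# Ancestor base at each variant position.
ancestor_at_variants <- function(aln) {
  aln$ancestor_full[aln$pos - aln$region_start + 1L]
}

# Logical: variant site lies in the high-quality mask.
variant_is_hq <- function(aln) {
  aln$hq_mask[aln$pos - aln$region_start + 1L]
}
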