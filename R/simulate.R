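# Synthetic-data generator. Genealogy-free: per-site derived-allele
# frequencies are drawn from a hierarchical Balding-Nichols cascade on the
# fixed population tree ((target, (backgroundA, backgroundB)), outgroup),
# then diploid phased haplotypes are sampled per individual. Structured
# signals (runs of homozygosity, selective sweeps, introgression, private
# non-synonymous variants) are planted on top and recorded in a truth
# object that downstream estimators are tested against.

#' Build a simulation configuration
#'
#' Defaults emulate a 3-ingroup + 1-outgroup study design: 4 target, 8 + 8
#' background individuals and a single outgroup individual, with a
#' mutation density of 2 SNPs/kb on a 2 x 5 Mb genome, derived-allele
#' frequencies drifted per branch, neutral conservation scores uniform on
#' [-2, 3.9] and deleterious ones on [4, 8].
#'
#' @param seed integer; fully determines the emitted bundle.
#' @param genome named vector of chromosome lengths (bp).
#' @param n_per_population named counts; must contain an `outgroup` of 1.
#' @param mutation_density expected SNPs per kb.
#' @param f_roh named per-population (or per-individual) target fraction of
#'   the genome planted as runs of homozygosity.
#' @param deleterious_fraction fraction of sites given a conservation score
#'   of at least 4.
#' @param migration fraction of target-individual allele draws taken from
#'   the backgroundA frequency instead of the target frequency (0 = none).
#' @param sweep_regions `data.frame` with columns chrom, start, end,
#'   population, diversity_reduction, or `NULL`.
#' @param n_genes,gene_length,cds_fraction,n_exons gene-model shape.
#' @param outgroup_ancestral_fraction probability the outgroup is
#'   homozygous ancestral at a site (>= 0.95).
#' @param ancestral_ref_prob probability the REF allele is the ancestral one.
#' @param drift named Balding-Nichols drift parameters for the branches
#'   root->target, root->(A,B) ancestor, ancestor->A, ancestor->B.
#' @param freq_shape Beta(a, b) prior on the derived-allele frequency at
#'   the ingroup root.
#' @param missing_rate per-genotype missingness probability.
#' @param n_private,n_fixed planted private / shared-background
#'   non-synonymous variant counts (the latter at background frequency
#'   `fixed_bg_freq`).
#' @param fixed_bg_freq background derived frequency of planted fixed-tier
#'   variants.
#' @param n_stop_gained how many planted private variants are converted to
#'   premature stop codons.
#' @param annotate logical; build a gene model and effect annotations.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chr1 = 5e6, chr2 = 5e6),
                       n_per_population = c(target = 4L, backgroundA = 8L,
                                            backgroundB = 8L, outgroup = 1L),
                       mutation_density = 2,
                       f_roh = c(target = 0, backgroundA = 0, backgroundB = 0),
                       deleterious_fraction = 0.05,
                       migration = 0,
                       sweep_regions = NULL,
                       n_genes = 30L, gene_length = 30000L,
                       cds_fraction = 0.5, n_exons = 5L,
                       outgroup_ancestral_fraction = 0.98,
                       ancestral_ref_prob = 0.9,
                       drift = c(target = 0.2, split = 0.05,
                                 backgroundA = 0.15, backgroundB = 0.15),
                       freq_shape = c(0.5, 2),
                       missing_rate = 0.02,
                       n_private = 4L, n_fixed = 2L, fixed_bg_freq = 0.0625,
                       n_stop_gained = 1L,
                       annotate = TRUE) {
  cfg <- as.list(environment())
  fr <- c(cfg$f_roh, cfg$deleterious_fraction, cfg$migration,
          cfg$missing_rate, cfg$cds_fraction, cfg$fixed_bg_freq,
          cfg$outgroup_ancestral_fraction, cfg$ancestral_ref_prob)
  stopifnot(all(fr >= 0 & fr <= 1),
            cfg$outgroup_ancestral_fraction >= 0.95,
            "outgroup" %in% names(cfg$n_per_population),
            cfg$n_per_population[["outgroup"]] == 1L,
            all(genome > 0), mutation_density > 0)
  if (!is.null(sweep_regions)) {
    sweep_regions <- as.data.frame(sweep_regions)
    stopifnot(all(c("chrom", "start", "end", "population",
                    "diversity_reduction") %in% names(sweep_regions)))
    ok <- sweep_regions$chrom %in% names(genome) &
      sweep_regions$end <= genome[sweep_regions$chrom] &
      sweep_regions$start >= 1
    if (!all(ok)) stop("sweep region outside the configured genome")
    if (migration > 0)
      stop("sweep regions cannot be combined with migration > 0 (confounded truth)")
    cfg$sweep_regions <- sweep_regions
  }
  needed_roh <- max(cfg$f_roh) * sum(genome)
  if (max(cfg$f_roh) > 0 && needed_roh > 0 && sum(genome) < 4e5)
    stop("genome too short to host the requested ROH fraction")
  class(cfg) <- "sim_config"
  cfg
}

balding_nichols <- function(p, c) {
  if (c <= 0) return(p)
  a <- p * (1 - c) / c
  b <- (1 - p) * (1 - c) / c
  q <- rbeta(length(p), a, b)
  # shape 0 degenerates; pin exactly fixed frequencies
  q[a == 0] <- 0
  q[b == 0] <- 1
  q
}

#' Plant runs of homozygosity into one individual's haplotypes
#'
#' Selects disjoint intervals (merged 200 kb tiles, so each interval is at
#' least 200 kb) whose summed length approximates `target_f_roh` of the
#' genome to within one tile, and copies haplotype 1 over haplotype 2
#' inside them. `target_f_roh = 1` homogenizes whole chromosomes. Uses the
#' current RNG state unless `seed` is given.
#'
#' @param h1,h2 0/1 haplotype vectors over the sites in `chrom`/`pos`.
#' @param chrom,pos site coordinates (1-based, sorted within chromosome).
#' @param genome named chromosome lengths (bp).
#' @param target_f_roh fraction of the genome to cover, in [0, 1].
#' @param seed optional integer seed.
#' @param tile_bp tile size; intervals are unions of adjacent tiles.
#' @return list with modified `h1`, `h2` and the planted `intervals`
#'   (`data.table`: chrom, start, end, 1-based inclusive).
#' @export
plant_roh <- function(h1, h2, chrom, pos, genome, target_f_roh,
                      seed = NULL, tile_bp = 2e5) {
  stopifnot(target_f_roh >= 0, target_f_roh <= 1)
  run <- function() {
    if (target_f_roh == 0)
      return(list(h1 = h1, h2 = h2,
                  intervals = data.table(chrom = character(),
                                         start = integer(), end = integer())))
    tiles <- rbindlist(lapply(names(genome), function(cn) {
      n_t <- floor(genome[[cn]] / tile_bp)
      if (n_t == 0L) return(NULL)
      data.table(chrom = cn,
                 start = as.integer((seq_len(n_t) - 1L) * tile_bp + 1L),
                 end = as.integer(seq_len(n_t) * tile_bp))
    }))
    if (target_f_roh == 1) {
      iv <- data.table(chrom = names(genome), start = 1L,
                       end = as.integer(unname(genome)))
    } else {
      k <- min(nrow(tiles), round(target_f_roh * sum(genome) / tile_bp))
      pick <- sort(sample.int(nrow(tiles), k))
      sel <- tiles[pick]
      # merge adjacent tiles into maximal intervals
      brk <- cumsum(c(1L, as.integer(diff(pick) != 1L |
                                       sel$chrom[-1] != sel$chrom[-nrow(sel)])))
      iv <- sel[, .(chrom = chrom[1], start = min(start), end = max(end)),
                by = .(grp = brk)][, !"grp"]
    }
    inside <- rep(FALSE, length(pos))
    for (r in seq_len(nrow(iv))) {
      inside <- inside | (chrom == iv$chrom[r] & pos >= iv$start[r] &
                            pos <= iv$end[r])
    }
    h2[inside] <- h1[inside]
    list(h1 = h1, h2 = h2, intervals = iv[, .(chrom, start, end)])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Plant a selective sweep into a population's haplotypes
#'
#' Inside `region`, one randomly chosen haplotype is copied into `k - 1`
#' of the population's other haplotypes where `k = round(n *
#' sqrt(1 - diversity_reduction))`, so the share of haplotype pairs that
#' remain distinct - and hence the region's nucleotide diversity - is
#' reduced to approximately `diversity_reduction` of its pre-sweep value.
#' `diversity_reduction = 1` leaves the haplotypes unchanged.
#'
#' @param haps 0/1 matrix, sites x haplotypes, for one population.
#' @param chrom,pos site coordinates matching rows of `haps`.
#' @param region list/row with `chrom`, `start`, `end` (1-based inclusive).
#' @param diversity_reduction factor in (0, 1].
#' @param seed optional integer seed.
#' @return list with modified `haps` and the `copied` haplotype indices.
#' @export
plant_sweep <- function(haps, chrom, pos, region, diversity_reduction,
                        seed = NULL) {
  stopifnot(diversity_reduction > 0, diversity_reduction <= 1)
  run <- function() {
    n <- ncol(haps)
    k <- round(n * sqrt(1 - diversity_reduction))
    if (k < 1L) return(list(haps = haps, copied = integer()))
    inside <- chrom == region$chrom & pos >= region$start & pos <= region$end
    donor <- sample.int(n, 1L)
    recipients <- if (k > 1L) sample(setdiff(seq_len(n), donor), k - 1L) else integer()
    haps[inside, recipients] <- haps[inside, donor]
    list(haps = haps, copied = sort(c(donor, recipients)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Place non-overlapping genes with evenly spaced exons; exon lengths are
# multiples of 3 so every gene's CDS is a whole number of codons. Every
# sweep region is guaranteed to host at least one fully contained gene
# (the planted sweep gene), so sweep-recovery truth is well defined.
build_gene_model_sim <- function(cfg) {
  genome <- cfg$genome
  slot_w <- 2L * cfg$gene_length
  slots <- rbindlist(lapply(names(genome), function(cn) {
    n_s <- floor(genome[[cn]] / slot_w)
    if (n_s == 0L) return(NULL)
    data.table(chrom = cn, slot_start = as.integer((seq_len(n_s) - 1L) * slot_w + 1L))
  }))
  n <- min(cfg$n_genes, nrow(slots))
  forced <- integer()
  if (!is.null(cfg$sweep_regions)) {
    for (r in seq_len(nrow(cfg$sweep_regions))) {
      reg <- cfg$sweep_regions[r, ]
      inside <- which(slots$chrom == reg$chrom &
                        slots$slot_start >= reg$start &
                        slots$slot_start + slot_w - 1L <= reg$end)
      if (length(inside) == 0L)
        stop("sweep region too small to host a gene (needs >= ",
             2 * cfg$gene_length, " bp aligned to the gene grid)")
      forced <- c(forced, inside[ceiling(length(inside) / 2)])
    }
  }
  free <- setdiff(seq_len(nrow(slots)), forced)
  pick <- sort(c(forced, sample(free, max(0L, n - length(forced)))))
  sel <- slots[pick]
  starts <- sel$slot_start + sample.int(cfg$gene_length %/% 2L, nrow(sel),
                                        replace = TRUE)
  n <- nrow(sel)
  exon_len <- 3L * max(1L, round(cfg$gene_length * cfg$cds_fraction /
                                   cfg$n_exons / 3))
  exon_gap <- (cfg$gene_length - cfg$n_exons * exon_len) %/% max(1L, cfg$n_exons)
  gene_id <- sprintf("GENE%03d", seq_len(n))
  lv <- names(genome)
  genes <- GenomicRanges::GRanges(
    factor(sel$chrom, levels = lv),
    IRanges::IRanges(starts, width = cfg$gene_length), gene_id = gene_id)
  exon_starts <- rep(starts, each = cfg$n_exons) +
    rep(seq_len(cfg$n_exons) - 1L, n) * (exon_len + exon_gap)
  cds <- GenomicRanges::GRanges(
    factor(rep(sel$chrom, each = cfg$n_exons), levels = lv),
    IRanges::IRanges(exon_starts, width = exon_len),
    gene_id = rep(gene_id, each = cfg$n_exons))
  gene_model(genes, cds)
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

# Effect annotation from the actual codon change, so coding_class agrees
# with a codon-table oracle. Sites outside CDS get MODIFIER terms.
annotate_sites_sim <- function(tab, model) {
  n <- nrow(tab)
  effect <- rep("intergenic_variant", n)
  impact <- rep("MODIFIER", n)
  gene <- rep("-", n)
  codon_pos <- rep(NA_integer_, n)
  ref_codon <- rep(NA_character_, n)

  sites <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$pos, width = 1L))
  og <- GenomicRanges::findOverlaps(sites, model$genes)
  effect[S4Vectors::queryHits(og)] <- "intron_variant"
  gene[S4Vectors::queryHits(og)] <- model$genes$gene_id[S4Vectors::subjectHits(og)]

  oc <- GenomicRanges::findOverlaps(sites, model$cds)
  qi <- S4Vectors::queryHits(oc); si <- S4Vectors::subjectHits(oc)
  if (length(qi)) {
    # cumulative CDS bp preceding each exon, per gene, in genomic order
    cds_dt <- data.table(gene = model$cds$gene_id,
                         start = GenomicRanges::start(model$cds),
                         width = GenomicRanges::width(model$cds))
    setorder(cds_dt, gene, start)
    cds_dt[, before := cumsum(c(0L, head(width, -1L))), by = gene]
    key <- paste(model$cds$gene_id, GenomicRanges::start(model$cds))
    before <- cds_dt$before[match(key, paste(cds_dt$gene, cds_dt$start))]

    off <- tab$pos[qi] - GenomicRanges::start(model$cds)[si] + before[si]
    cp <- off %% 3L  # 0-based position within codon
    ctx <- matrix(sample(BASES, 2L * length(qi), replace = TRUE), ncol = 2L)
    mk <- function(b, p, c1, c2) {
      out <- character(length(b))
      out[p == 0L] <- paste0(b[p == 0L], c1[p == 0L], c2[p == 0L])
      out[p == 1L] <- paste0(c1[p == 1L], b[p == 1L], c2[p == 1L])
      out[p == 2L] <- paste0(c1[p == 2L], c2[p == 2L], b[p == 2L])
      out
    }
    rc <- mk(tab$ref[qi], cp, ctx[, 1], ctx[, 2])
    # forbid reference stop codons: resample context where one was drawn
    for (it in 1:20) {
      bad <- rc %in% STOPS
      if (!any(bad)) break
      ctx[bad, ] <- sample(BASES, 2L * sum(bad), replace = TRUE)
      rc <- mk(tab$ref[qi], cp, ctx[, 1], ctx[, 2])
    }
    ac <- mk(tab$alt[qi], cp, ctx[, 1], ctx[, 2])
    aa_r <- codon_aa(rc); aa_a <- codon_aa(ac)
    eff <- ifelse(aa_a == "*", "stop_gained",
                  ifelse(aa_r == aa_a, "synonymous_variant", "missense_variant"))
    imp <- c(stop_gained = "HIGH", synonymous_variant = "LOW",
             missense_variant = "MODERATE")[eff]
    effect[qi] <- eff
    impact[qi] <- unname(imp)
    gene[qi] <- model$cds$gene_id[si]
    codon_pos[qi] <- cp
    ref_codon[qi] <- rc
  }
  ann <- data.table(site_id = tab$site_id, gene_id = gene, effect_term = effect,
                    impact = impact, coding_class = coding_class_of(effect))
  list(ann = ann, codon_pos = codon_pos, ref_codon = ref_codon)
}

#' Simulate a complete analysis-ready dataset
#'
#' Draws sites, per-population derived-allele frequencies, phased
#' genotypes, conservation scores, a gene model with codon-consistent
#' effect annotations, then plants the configured runs of homozygosity,
#' sweeps and private non-synonymous variants. The same seed always
#' produces the same dataset.
#'
#' @param config a [sim_config()].
#' @return a `karst_sim` list: `table` (variant_table), `geno`
#'   (genotype_matrix), `popmap`, `haplotypes` (list h1, h2: 0/1 matrices,
#'   sites x individuals), `gene_model`, `genome`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  genome <- cfg$genome
  # --- sites ---------------------------------------------------------------
  per_chrom <- lapply(names(genome), function(cn) {
    n <- rpois(1L, genome[[cn]] / 1000 * cfg$mutation_density)
    n <- min(n, genome[[cn]])
    sort(sample.int(genome[[cn]], n))
  })
  chrom <- rep(names(genome), lengths(per_chrom))
  pos <- unlist(per_chrom, use.names = FALSE)
  n <- length(pos)
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
  anc_is_ref <- runif(n) < cfg$ancestral_ref_prob

  pops <- names(cfg$n_per_population)
  ingroups <- setdiff(pops, "outgroup")
  ind_ids <- unlist(lapply(ingroups, function(p)
    sprintf("%s_%d", p, seq_len(cfg$n_per_population[[p]]))), use.names = FALSE)
  ind_pop <- rep(ingroups, cfg$n_per_population[ingroups])
  out_id <- "outgroup_1"

  draw_freqs <- function(m) {
    p_root <- rbeta(m, cfg$freq_shape[1], cfg$freq_shape[2])
    p_ab <- balding_nichols(p_root, cfg$drift[["split"]])
    list(target = balding_nichols(p_root, cfg$drift[["target"]]),
         backgroundA = balding_nichols(p_ab, cfg$drift[["backgroundA"]]),
         backgroundB = balding_nichols(p_ab, cfg$drift[["backgroundB"]]))
  }

  draw_block <- function(idx) {
    m <- length(idx)
    fr <- draw_freqs(m)
    # derived -> alt-allele orientation
    p_alt <- lapply(fr, function(p) ifelse(anc_is_ref[idx], p, 1 - p))
    h1 <- matrix(0L, m, length(ind_ids)); h2 <- matrix(0L, m, length(ind_ids))
    for (j in seq_along(ind_ids)) {
      p <- p_alt[[ind_pop[j]]]
      if (ind_pop[j] == "target" && cfg$migration > 0)
        p <- (1 - cfg$migration) * p + cfg$migration * p_alt[["backgroundA"]]
      h1[, j] <- rbinom(m, 1L, p)
      h2[, j] <- rbinom(m, 1L, p)
    }
    og_anc <- runif(m) < cfg$outgroup_ancestral_fraction
    og_alt_dose <- ifelse(og_anc == anc_is_ref[idx], 0L, 1L)  # per haplotype
    list(h1 = h1, h2 = h2, og = og_alt_dose)
  }

  blk <- draw_block(seq_len(n))
  h1 <- blk$h1; h2 <- blk$h2; og <- blk$og
  # resample sample-monomorphic-REF sites so the emitted SNP count keeps
  # its Poisson distribution
  for (it in 1:25) {
    mono <- rowSums(h1) + rowSums(h2) + 2L * og == 0L
    if (!any(mono)) break
    idx <- which(mono)
    nb <- draw_block(idx)
    h1[idx, ] <- nb$h1; h2[idx, ] <- nb$h2; og[idx] <- nb$og
  }

  # --- planted runs of homozygosity ---------------------------------------
  f_roh_ind <- if (!is.null(names(cfg$f_roh)) &&
                   all(names(cfg$f_roh) %in% ingroups)) {
    setNames(cfg$f_roh[ind_pop], ind_ids)
  } else {
    stopifnot(all(names(cfg$f_roh) %in% ind_ids))
    setNames(ifelse(is.na(cfg$f_roh[ind_ids]), 0, cfg$f_roh[ind_ids]), ind_ids)
  }
  roh_truth <- vector("list", length(ind_ids))
  names(roh_truth) <- ind_ids
  for (j in seq_along(ind_ids)) {
    pl <- plant_roh(h1[, j], h2[, j], chrom, pos, genome, f_roh_ind[[j]])
    h1[, j] <- pl$h1; h2[, j] <- pl$h2
    roh_truth[[j]] <- pl$intervals
  }

  # --- planted sweeps ------------------------------------------------------
  sweep_genes <- character()
  if (!is.null(cfg$sweep_regions)) {
    for (r in seq_len(nrow(cfg$sweep_regions))) {
      reg <- cfg$sweep_regions[r, ]
      cols <- which(ind_pop == reg$population)
      haps <- cbind(h1[, cols, drop = FALSE], h2[, cols, drop = FALSE])
      sw <- plant_sweep(haps, chrom, pos, reg, reg$diversity_reduction)
      h1[, cols] <- sw$haps[, seq_along(cols), drop = FALSE]
      h2[, cols] <- sw$haps[, length(cols) + seq_along(cols), drop = FALSE]
    }
  }

  # --- conservation scores -------------------------------------------------
  gerp <- runif(n, -2, 3.9)
  n_del <- round(cfg$deleterious_fraction * n)
  del_idx <- sample.int(n, n_del)
  gerp[del_idx] <- runif(n_del, 4, 8)

  # --- gene model & annotation --------------------------------------------
  tab <- variant_table(chrom, pos, ref, alt,
                       ancestral = ifelse(anc_is_ref, ref, alt), gerp = gerp)
  model <- NULL; codon_pos <- NULL; ref_codon <- NULL
  if (cfg$annotate) {
    model <- build_gene_model_sim(cfg)
    anno <- annotate_sites_sim(tab, model)
    codon_pos <- anno$codon_pos; ref_codon <- anno$ref_codon
    ann <- anno$ann
  } else {
    ann <- NULL
  }

  # --- planted private / fixed-tier non-synonymous variants ----------------
  planted_private <- character(); planted_fixed <- character()
  planted_stop <- character()
  t_cols <- which(ind_pop == "target")
  b_cols <- which(ind_pop != "target")
  if (cfg$annotate && length(t_cols)) {
    ns <- which(ann$coding_class == "non_synonymous" &
                  ann$effect_term == "missense_variant")
    n_want <- cfg$n_private + cfg$n_fixed
    if (length(ns) >= n_want) {
      pick <- sample(ns, n_want)
      priv <- pick[seq_len(cfg$n_private)]
      fixd <- pick[cfg$n_private + seq_len(cfg$n_fixed)]
      for (i in c(priv, fixd)) {
        h1[i, t_cols] <- 1L; h2[i, t_cols] <- 1L
        h1[i, b_cols] <- 0L; h2[i, b_cols] <- 0L
        og[i] <- 0L
        anc_is_ref[i] <- TRUE
        tab$ancestral[i] <- tab$ref[i]
      }
      n_bg_hap <- 2L * length(b_cols)
      k_bg <- max(1L, round(cfg$fixed_bg_freq * n_bg_hap))
      for (i in fixd) {
        slots <- sample.int(n_bg_hap, k_bg)
        for (s in slots) {
          col <- b_cols[ceiling(s / 2)]
          if (s %% 2L == 1L) h1[i, col] <- 1L else h2[i, col] <- 1L
        }
      }
      # convert some planted private variants to premature stop codons:
      # REF T / ALT A at codon position 3 in context "TA-" gives TAT->TAA
      n_stop <- min(cfg$n_stop_gained, length(priv))
      if (n_stop > 0L) {
        for (i in priv[seq_len(n_stop)]) {
          tab$ref[i] <- "T"; tab$alt[i] <- "A"
          tab$ancestral[i] <- "T"
          gi <- ann$gene_id[i]
          ann[i, `:=`(effect_term = "stop_gained", impact = "HIGH",
                      coding_class = "non_synonymous")]
          codon_pos[i] <- 2L; ref_codon[i] <- "TAT"
          planted_stop <- c(planted_stop, tab$site_id[i])
        }
      }
      planted_private <- tab$site_id[priv]
      planted_fixed <- tab$site_id[fixd]
    }
  }
  if (!is.null(ann)) set_annotations(tab, ann)

  # --- assemble genotypes --------------------------------------------------
  g_in <- h1 + h2
  og_geno <- 2L * og  # outgroup is always homozygous by construction
  g <- cbind(g_in, og_geno)
  colnames(g) <- c(ind_ids, out_id)
  oh1 <- og; oh2 <- og
  H1 <- cbind(h1, oh1); H2 <- cbind(h2, oh2)
  colnames(H1) <- colnames(H2) <- colnames(g)
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(length(g)) < cfg$missing_rate, nrow = n)
    # never mask planted screen sites in any individual
    keep_rows <- tab$site_id %in% c(planted_private, planted_fixed)
    miss[keep_rows, ] <- FALSE
    g[miss] <- NA_integer_
  }

  popmap <- data.table(individual = colnames(g),
                       population = c(ind_pop, "outgroup"),
                       role = c(ifelse(ind_pop == "target", "target",
                                       "background"), "outgroup"))
  callable <- setNames(rep(sum(genome), ncol(g)), colnames(g))
  geno <- genotype_matrix(g, colnames(g), callable_length = callable)

  sweep_genes_partial <- character()
  if (!is.null(cfg$sweep_regions) && !is.null(model)) {
    sw_gr <- GenomicRanges::GRanges(cfg$sweep_regions$chrom,
                                    IRanges::IRanges(cfg$sweep_regions$start,
                                                     cfg$sweep_regions$end))
    win <- GenomicRanges::findOverlaps(model$genes, sw_gr, type = "within")
    sweep_genes <- unique(model$genes$gene_id[S4Vectors::queryHits(win)])
    any_hit <- GenomicRanges::findOverlaps(model$genes, sw_gr)
    sweep_genes_partial <- unique(model$genes$gene_id[S4Vectors::queryHits(any_hit)])
  }

  truth <- build_truth(tab, geno, popmap, roh_truth, genome, cfg,
                       planted_private, planted_fixed, planted_stop,
                       sweep_genes, sweep_genes_partial)
  structure(list(table = tab, geno = geno, popmap = popmap,
                 haplotypes = list(h1 = H1, h2 = H2),
                 gene_model = model, genome = genome, truth = truth,
                 codon_pos = codon_pos, ref_codon = ref_codon,
                 config = cfg),
            class = "karst_sim")
}

# Ground truth, recomputed from the emitted data with straight-line code:
# the load numbers replicate the pipeline contract (shared-site filter over
# the ingroup species, outgroup polarization, GERP >= 4) and the screen
# sets are found by scanning the genotypes, so accidental qualifying sites
# are part of the truth, not an error.
build_truth <- function(tab, geno, popmap, roh_truth, genome, cfg,
                        planted_private, planted_fixed, planted_stop,
                        sweep_genes, sweep_genes_partial) {
  g <- unclass(geno)
  ingroup <- popmap$individual[popmap$role != "outgroup"]
  out_ind <- popmap$individual[popmap$role == "outgroup"]
  gi <- g[, ingroup, drop = FALSE]

  # shared-site filter: drop sites where every called ingroup genotype is
  # the same homozygote
  mx <- apply(gi, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0L && all(r == r[1]) && r[1] != 1L
  })
  keep <- !mx

  og <- g[, out_ind]
  derived_is_alt <- og == 0L
  polarizable <- !is.na(og) & og != 1L

  del <- !is.na(tab$gerp) & tab$gerp >= 4
  masked <- realized <- setNames(numeric(length(ingroup)), ingroup)
  for (ind in ingroup) {
    gv <- g[, ind]
    called <- keep & !is.na(gv)
    use <- called & polarizable & del
    het <- use & gv == 1L
    hom_der <- use & ((derived_is_alt & gv == 2L) | (!derived_is_alt & gv == 0L))
    n_called <- sum(called)
    masked[ind] <- sum(tab$gerp[het]) / n_called
    realized[ind] <- sum(tab$gerp[hom_der]) / n_called
  }

  # screen truth: scan for qualifying non-synonymous sites
  t_ind <- popmap$individual[popmap$role == "target"]
  b_ind <- setdiff(ingroup, t_ind)
  ns <- !is.na(tab$coding_class) & tab$coding_class == "non_synonymous"
  gt <- g[, t_ind, drop = FALSE]
  all_hom_alt <- rowSums(gt == 2L, na.rm = TRUE) == length(t_ind) &
    rowSums(is.na(gt)) == 0L
  gb <- g[, b_ind, drop = FALSE]
  bg_freq <- rowSums(gb, na.rm = TRUE) / (2L * rowSums(!is.na(gb)))
  bg_freq[is.nan(bg_freq)] <- 0
  qual <- ns & all_hom_alt
  truth_private <- tab$site_id[qual & bg_freq == 0]
  truth_fixed <- tab$site_id[qual & bg_freq <= 0.2895]
  sg <- !is.na(tab$effect_term) & tab$effect_term == "stop_gained"
  truth_stop <- tab$site_id[sg & all_hom_alt]

  f_roh_true <- vapply(roh_truth, function(iv) {
    if (nrow(iv) == 0L) return(0)
    sum(iv$end - iv$start + 1) / sum(genome)
  }, 0)

  list(seed = cfg$seed,
       migration = cfg$migration,
       introgression = if (cfg$migration == 0) "none" else
         sprintf("backgroundA->target fraction %g", cfg$migration),
       genome = as.list(genome),
       ancestral = tab$ancestral,
       site_id = tab$site_id,
       roh_intervals = roh_truth,
       f_roh = f_roh_true,
       masked_load = masked,
       realized_load = realized,
       sweep_genes = sweep_genes,
       sweep_genes_partial = sweep_genes_partial,
       planted_private = planted_private,
       planted_fixed = planted_fixed,
       planted_stop_gained = planted_stop,
       private_sites = truth_private,
       fixed_sites = truth_fixed,
       stop_gained_sites = truth_stop)
}

#' Write a simulated dataset to an analysis-ready file bundle
#'
#' Emits `data.vcf` (phased genotypes with ANN annotations), `genes.gff3`,
#' `gerp.tsv`, `popmap.tsv`, `callable.tsv` and `truth.json`. Output is
#' plain text and byte-deterministic for a given configuration.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "data.vcf"),
             gff = file.path(dir, "genes.gff3"),
             gerp = file.path(dir, "gerp.tsv"),
             popmap = file.path(dir, "popmap.tsv"),
             callable = file.path(dir, "callable.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$table, sim$geno, paths[["vcf"]], haplotypes = sim$haplotypes,
            chrom_lengths = sim$genome)
  if (!is.null(sim$gene_model)) write_gene_model(sim$gene_model, paths[["gff"]])
  fwrite(sim$table[, .(chrom, pos, gerp)], paths[["gerp"]], sep = "\t",
         col.names = FALSE)
  fwrite(sim$popmap, paths[["popmap"]], sep = "\t", col.names = FALSE)
  cl <- callable_length(sim$geno)
  fwrite(data.table(individual = names(cl), callable_bp = as.integer(cl)),
         paths[["callable"]], sep = "\t", col.names = FALSE)
  truth <- sim$truth
  truth$roh_intervals <- lapply(truth$roh_intervals, as.data.frame)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = FALSE)
  invisible(paths)
}
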