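# Shared data model and readers/writers for the standard input formats:
# multi-sample VCF (gzip-aware), GFF3 gene models, a 3-column conservation
# score track, a 2-3 column population map and a per-individual callability
# table. Coordinates are 1-based inclusive throughout (VCF/GFF/IRanges
# convention); BED-style report writers convert on output.

GENO_CODES <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)

#' Fixed effect-term to coding-class mapping
#'
#' Versioned lookup used to derive `coding_class` from an annotation's
#' effect term: `missense_variant`, `stop_gained`, `stop_lost` and
#' `start_lost` are non-synonymous; `synonymous_variant` and
#' `stop_retained_variant` are synonymous; everything else is `other`.
#'
#' @return named character vector with attribute `version`.
#' @export
coding_class_map <- function() {
  m <- c(
    missense_variant      = "non_synonymous",
    stop_gained           = "non_synonymous",
    stop_lost             = "non_synonymous",
    start_lost            = "non_synonymous",
    synonymous_variant    = "synonymous",
    stop_retained_variant = "synonymous"
  )
  attr(m, "version") <- "1"
  m
}

coding_class_of <- function(effect_term) {
  m <- coding_class_map()
  cls <- unname(m[effect_term])
  cls[is.na(cls)] <- "other"
  cls
}

#' Construct a variant table
#'
#' A `variant_table` is a `data.table` of per-site records (chrom, pos, ref,
#' alt, ancestral, gerp) carrying the full effect-annotation set in the
#' `ann` attribute plus, per site, the most severe annotation's columns
#' (`effect_term`, `impact`, `coding_class`, `gene_id`).
#'
#' @param chrom,pos,ref,alt site coordinates and alleles (pos 1-based).
#' @param ancestral ancestral allele per site or `NA` (unknown).
#' @param gerp conservation score per site or `NA` (absent).
#' @param ann optional annotation `data.frame` with columns `site_id`,
#'   `gene_id`, `effect_term`, `impact`, `coding_class`.
#' @return a `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, ancestral = NA_character_,
                          gerp = NA_real_, ann = NULL) {
  tab <- data.table(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    ancestral = rep_len(as.character(ancestral), length(pos)),
    gerp = rep_len(as.numeric(gerp), length(pos))
  )
  tab[, site_id := site_id(chrom, pos)]
  setattr(tab, "class", c("variant_table", class(data.table())))
  set_annotations(tab, ann)
}

empty_ann <- function() {
  data.table(site_id = character(), gene_id = character(),
             effect_term = character(), impact = character(),
             coding_class = character())
}

# Attach/replace the annotation set and refresh the per-site most-severe
# annotation columns (HIGH > MODERATE > LOW > MODIFIER).
set_annotations <- function(tab, ann) {
  ann <- if (is.null(ann) || nrow(ann) == 0L) empty_ann() else as.data.table(ann)
  ann <- ann[ann$site_id %in% tab$site_id, ]
  setattr(tab, "ann", ann)
  tab[, `:=`(effect_term = NA_character_, impact = NA_character_,
             coding_class = NA_character_, gene_id = NA_character_)]
  if (nrow(ann)) {
    top <- ann[order(impact_rank(impact))][!duplicated(site_id)]
    idx <- match(top$site_id, tab$site_id)
    tab[idx, `:=`(effect_term = top$effect_term, impact = top$impact,
                  coding_class = top$coding_class, gene_id = top$gene_id)]
  }
  tab
}

#' Annotations attached to a variant table
#' @param tab a `variant_table`.
#' @return annotation `data.table` (site_id, gene_id, effect_term, impact,
#'   coding_class), one row per annotation.
#' @export
annotations <- function(tab) attr(tab, "ann") %||% empty_ann()

# Subset a variant table by row index/logical, keeping annotations in sync.
vt_subset <- function(tab, keep) {
  out <- tab[keep]
  setattr(out, "class", class(tab))
  set_annotations(out, annotations(tab))
  out
}

#' Construct a genotype matrix
#'
#' Sites x individuals diploid genotype codes: 0 = hom ref, 1 = het,
#' 2 = hom alt, `NA` = missing. `callable_length` is the per-individual
#' number of confidently called bases (variant plus invariant) used as a
#' denominator for per-bp rates; when absent it defaults to the number of
#' variant sites, with a warning.
#'
#' @param g integer matrix (sites x individuals).
#' @param individual_ids column names.
#' @param callable_length named numeric vector of callable bp, or `NULL`.
#' @return integer matrix with class `genotype_matrix`.
#' @export
genotype_matrix <- function(g, individual_ids = colnames(g),
                            callable_length = NULL) {
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  stopifnot(all(g %in% c(0L, 1L, 2L, NA_integer_)))
  colnames(g) <- individual_ids
  if (is.null(callable_length)) {
    warning("no callability input; callable_length defaults to the number of variant sites")
    callable_length <- setNames(rep(nrow(g), ncol(g)), individual_ids)
  }
  stopifnot(all(individual_ids %in% names(callable_length)))
  attr(g, "callable_length") <- callable_length[individual_ids]
  class(g) <- c("genotype_matrix", class(g))
  g
}

#' Per-individual callable length (bp)
#' @param geno a `genotype_matrix`.
#' @return named numeric vector.
#' @export
callable_length <- function(geno) attr(geno, "callable_length")

#' Parse a snpEff-style ANN field
#'
#' Entries are comma-separated; each entry is pipe-delimited with the
#' effect term first, the impact category second and the gene id fourth
#' (`effect|impact|detail|gene|...`). `coding_class` is derived from the
#' effect term via [coding_class_map()]. Malformed entries (fewer than four
#' fields, or an impact outside HIGH/MODERATE/LOW/MODIFIER) are skipped
#' with a warning, never silently dropped.
#'
#' @param ann_field the raw ANN string for one site.
#' @return `data.table` with one row per well-formed entry: `gene_id`,
#'   `effect_term`, `impact`, `coding_class`.
#' @export
parse_effect_annotation <- function(ann_field) {
  out <- empty_ann()[, !"site_id"]
  if (is.na(ann_field) || !nzchar(ann_field)) return(out)
  entries <- strsplit(ann_field, ",", fixed = TRUE)[[1]]
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(f) < 4L || !f[2] %in% IMPACT_LEVELS) {
      warning("skipping malformed annotation entry: ", e)
      return(NULL)
    }
    data.table(gene_id = f[4], effect_term = f[1], impact = f[2],
               coding_class = coding_class_of(f[1]))
  })
  rbindlist(c(list(out), rows))
}

#' Read a population map
#'
#' Tab-separated, two or three columns: individual, population and an
#' optional role (`target`, `background` or `outgroup`; default
#' `background`).
#'
#' @param path file path.
#' @return `data.table` (individual, population, role).
#' @export
read_popmap <- function(path) {
  pm <- fread(path, header = FALSE)
  if (ncol(pm) < 2L) stop("popmap needs at least 2 columns")
  if (ncol(pm) == 2L) pm[, V3 := "background"]
  pm <- pm[, 1:3]
  setnames(pm, c("individual", "population", "role"))
  bad <- setdiff(pm$role, c("target", "background", "outgroup"))
  if (length(bad)) stop("unknown popmap role(s): ", paste(bad, collapse = ", "))
  pm
}

#' Read a conservation-score track
#'
#' Three tab-separated columns: chrom, pos (1-based), score. Duplicate
#' (chrom, pos) records are a hard error.
#'
#' @param path file path.
#' @return `data.table` (chrom, pos, gerp).
#' @export
read_gerp <- function(path) {
  g <- fread(path, header = FALSE, col.names = c("chrom", "pos", "gerp"))
  g[, chrom := as.character(chrom)]
  if (anyDuplicated(g[, .(chrom, pos)]))
    stop("duplicate (chrom, pos) records in conservation track: ", path)
  g
}

#' Read a gene model from GFF3
#'
#' Keeps `gene` and `CDS` features; gene ids are taken from the `ID`
#' attribute of gene records and the `Parent` attribute of CDS records.
#'
#' @param path GFF3 file.
#' @return a `gene_model`: list of `GRanges` (`genes`, `cds`), each with a
#'   `gene_id` metadata column.
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path)
  genes <- gr[gr$type == "gene"]
  genes$gene_id <- as.character(genes$ID)
  cds <- gr[gr$type == "CDS"]
  parent <- as.character(S4Vectors::unstrsplit(cds$Parent, ","))
  cds$gene_id <- sub("^(gene:)?", "", parent)
  gene_model(genes, cds)
}

#' Construct a gene model from ranges
#' @param genes,cds `GRanges` with a `gene_id` metadata column.
#' @return a `gene_model` object.
#' @export
gene_model <- function(genes, cds) {
  structure(list(genes = genes, cds = cds), class = "gene_model")
}

gt_to_code <- function(gt) {
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  out <- map[gt]
  unname(out)
}

#' Read a multi-sample VCF into the shared data model
#'
#' Reads variants (gzip-aware), joins an optional conservation-score track
#' by exact (chrom, pos) match (absent positions carry `NA`), parses ANN
#' effect annotations and attaches per-individual callable lengths. Sites
#' are ordered by (chrom, pos). A VCF sample missing from the popmap is a
#' hard error naming the sample.
#'
#' @param vcf_path multi-sample VCF (optionally gzipped).
#' @param popmap_path population map covering all VCF samples.
#' @param gerp_path optional 3-column score track.
#' @param callable_path optional 2-column per-individual callable-bp table.
#' @return list with `table` ([variant_table()]), `geno`
#'   ([genotype_matrix()]), `popmap` and `haplotypes` (phased 0/1 matrices
#'   `h1`/`h2`, or `NULL` when any called genotype is unphased).
#' @export
read_variant_table <- function(vcf_path, popmap_path, gerp_path = NULL,
                               callable_path = NULL) {
  popmap <- read_popmap(popmap_path)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(S4Vectors::unstrsplit(
    methods::as(VariantAnnotation::alt(vcf), "CharacterList"), ","))
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)

  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  missing_pm <- setdiff(samples, popmap$individual)
  if (length(missing_pm))
    stop("VCF sample(s) missing from popmap: ", paste(missing_pm, collapse = ", "))

  g <- matrix(gt_to_code(gt), nrow = nrow(gt), dimnames = list(NULL, samples))

  # phased haplotypes, kept only when every called genotype is phased
  phased <- all(grepl("|", gt[!is.na(g)], fixed = TRUE))
  haplotypes <- NULL
  if (phased) {
    a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
    a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
    haplotypes <- list(h1 = matrix(a1, nrow = nrow(gt),
                                   dimnames = list(NULL, samples)),
                       h2 = matrix(a2, nrow = nrow(gt),
                                   dimnames = list(NULL, samples)))
  }

  ann_raw <- rep(NA_character_, length(pos))
  info <- VariantAnnotation::info(vcf)
  if ("ANN" %in% colnames(info)) {
    al <- info$ANN
    has <- lengths(al) > 0
    ann_raw[has] <- as.character(S4Vectors::unstrsplit(al[has], ","))
  }

  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  if (!is.null(haplotypes)) {
    haplotypes$h1 <- haplotypes$h1[ord, , drop = FALSE]
    haplotypes$h2 <- haplotypes$h2[ord, , drop = FALSE]
  }
  tab <- variant_table(chrom, pos,
                       ref = as.character(VariantAnnotation::ref(vcf))[ord],
                       alt = alt[ord])
  g <- g[ord, , drop = FALSE]
  ann_raw <- ann_raw[ord]

  parsed <- lapply(seq_along(ann_raw), function(i) {
    a <- parse_effect_annotation(ann_raw[i])
    if (nrow(a)) a[, site_id := tab$site_id[i]]
    a
  })
  ann <- rbindlist(parsed, fill = TRUE)
  if (nrow(ann)) {
    setcolorder(ann, c("site_id", "gene_id", "effect_term", "impact",
                       "coding_class"))
    set_annotations(tab, ann)
  }

  if (!is.null(gerp_path)) {
    gtrack <- read_gerp(gerp_path)
    idx <- match(tab$site_id, site_id(gtrack$chrom, gtrack$pos))
    tab[, gerp := gtrack$gerp[idx]]
  }

  callable <- NULL
  if (!is.null(callable_path)) {
    ct <- fread(callable_path, header = FALSE, col.names = c("individual", "callable_bp"))
    callable <- setNames(ct$callable_bp, ct$individual)
  }
  geno <- genotype_matrix(g, samples, callable_length = callable)
  list(table = tab, geno = geno, popmap = popmap, haplotypes = haplotypes)
}

#' Apply the study's site-level filters
#'
#' Retains biallelic SNPs (single-base ref and alt, ref != alt) whose
#' missing-genotype fraction over all individuals does not exceed
#' `max_missing`. Site order is preserved, filter counts are reported via
#' `message()`, and the operation is idempotent.
#'
#' @param table a `variant_table`.
#' @param geno matching `genotype_matrix`.
#' @param max_missing maximum tolerated missing fraction (default 0.10;
#'   sites with *more* than 10 percent missing genotypes are removed).
#' @param biallelic_snps_only drop indels and multi-allelic records.
#' @return list with filtered `table` and `geno`.
#' @export
filter_sites <- function(table, geno, max_missing = 0.10,
                         biallelic_snps_only = TRUE) {
  stopifnot(nrow(table) == nrow(geno))
  keep <- rep(TRUE, nrow(table))
  if (biallelic_snps_only) {
    bases <- c("A", "C", "G", "T")
    keep <- keep & table$ref %in% bases & table$alt %in% bases &
      table$ref != table$alt
  }
  n_snp_fail <- sum(!keep)
  miss <- rowMeans(is.na(unclass(geno)))
  keep_miss <- miss <= max_missing
  message(sprintf("filter_sites: removed %d non-biallelic-SNP and %d high-missingness sites; %d retained",
                  n_snp_fail, sum(keep & !keep_miss), sum(keep & keep_miss)))
  keep <- keep & keep_miss
  if (!any(keep)) warning("filter_sites: no sites retained")
  out_g <- unclass(geno)[keep, , drop = FALSE]
  list(table = vt_subset(table, keep),
       geno = genotype_matrix(out_g, colnames(geno), callable_length(geno)))
}

#' Write the data model back to VCF
#'
#' Emits a minimal VCFv4.2 file (gzipped when `path` ends in `.gz`) whose
#' sites, genotypes and annotations round-trip through
#' [read_variant_table()]. Genotypes are written unphased unless a phased
#' haplotype pair is supplied.
#'
#' @param table a `variant_table`.
#' @param geno matching `genotype_matrix`.
#' @param path output path.
#' @param haplotypes optional list of two 0/1 matrices (`h1`, `h2`) to emit
#'   phased genotypes.
#' @param chrom_lengths optional named vector for contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, geno, path, haplotypes = NULL,
                      chrom_lengths = NULL) {
  samples <- colnames(geno)
  g <- unclass(geno)
  if (is.null(haplotypes)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
    gt[is.na(g)] <- "./."
  } else {
    gt <- matrix(paste0(haplotypes$h1, "|", haplotypes$h2), nrow = nrow(g))
    gt[is.na(g)] <- ".|."
  }
  ann_tab <- annotations(table)
  info <- rep(".", nrow(table))
  if (nrow(ann_tab)) {
    ann_str <- ann_tab[, .(s = paste(sprintf("%s|%s|.|%s|t1", effect_term,
                                             impact, gene_id),
                                     collapse = ",")), by = site_id]
    idx <- match(table$site_id, ann_str$site_id)
    info <- ifelse(is.na(idx), ".", paste0("ANN=", ann_str$s[idx]))
  }
  chroms <- unique(table$chrom)
  contig <- if (is.null(chrom_lengths)) {
    sprintf("##contig=<ID=%s>", chroms)
  } else {
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths))
  }
  hdr <- c("##fileformat=VCFv4.2", contig,
           "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'effect|impact|detail|gene|transcript'\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(table$chrom, table$pos, ".", table$ref, table$alt, ".",
                "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Write a gene model as GFF3
#' @param model a `gene_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  gene_lines <- sprintf("%s\tkarstpop\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                        as.character(GenomicRanges::seqnames(model$genes)),
                        GenomicRanges::start(model$genes),
                        GenomicRanges::end(model$genes),
                        model$genes$gene_id)
  ncds <- length(model$cds)
  cds_lines <- if (ncds) {
    sprintf("%s\tkarstpop\tCDS\t%d\t%d\t.\t+\t0\tID=cds-%s-%d;Parent=%s",
            as.character(GenomicRanges::seqnames(model$cds)),
            GenomicRanges::start(model$cds), GenomicRanges::end(model$cds),
            model$cds$gene_id, seq_len(ncds), model$cds$gene_id)
  } else character()
  writeLines(c("##gff-version 3", gene_lines, cds_lines), path)
  invisible(path)
}
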