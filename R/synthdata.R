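#' Simulation design for a balanced line x sex x treatment expression study
#'
#' Encodes the factorial model on the log2 scale: fixed sex, treatment and
#' Wolbachia shifts plus independent Gaussian random draws for line,
#' sex-by-line, treatment-by-line and sex-by-treatment-by-line terms, with
#' i.i.d. residual noise per sample. Only a fraction `frac_lxt` of
#' transcripts carries nonzero line-by-treatment variance, so ground truth
#' distinguishes genuinely treatment-responsive transcripts from nulls.
#'
#' @param n_lines,n_transcripts,n_replicates design sizes; `n_replicates` is
#'   per line x sex x treatment cell and must be >= 2.
#' @param sd_line,sd_sexline,sd_treatline,sd_sextreatline,sd_resid standard
#'   deviations of the random terms, log2 units.
#' @param sex_effect,treatment_effect fixed shifts (log2 units) applied to
#'   males and to the ethanol condition respectively.
#' @param frac_lxt fraction of transcripts with nonzero line-by-treatment sd.
#' @param wolbachia_frac fraction of lines carrying the infection.
#' @param wolbachia_effect fixed log2 shift for infected lines.
#' @param seed integer seed.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(n_lines = 20, n_transcripts = 500, n_replicates = 2,
                       sd_line = 0.5, sd_sexline = 0.25, sd_treatline = 0.5,
                       sd_sextreatline = 0, sd_resid = 0.5,
                       sex_effect = 1, treatment_effect = 0.5,
                       frac_lxt = 0.1, wolbachia_frac = 0.5,
                       wolbachia_effect = 0.2, seed = 1L) {
  if (n_lines < 1 || n_transcripts < 1)
    stop("invalid design: n_lines and n_transcripts must be positive")
  stopifnot_scalar(n_replicates, "n_replicates", 2)
  for (nm in c("sd_line", "sd_sexline", "sd_treatline", "sd_sextreatline",
               "sd_resid"))
    stopifnot_scalar(get(nm), nm, 0)
  stopifnot_scalar(frac_lxt, "frac_lxt", 0, 1)
  stopifnot_scalar(wolbachia_frac, "wolbachia_frac", 0, 1)
  structure(list(n_lines = as.integer(n_lines),
                 n_transcripts = as.integer(n_transcripts),
                 n_replicates = as.integer(n_replicates),
                 sd_line = sd_line, sd_sexline = sd_sexline,
                 sd_treatline = sd_treatline,
                 sd_sextreatline = sd_sextreatline, sd_resid = sd_resid,
                 sex_effect = sex_effect, treatment_effect = treatment_effect,
                 frac_lxt = frac_lxt, wolbachia_frac = wolbachia_frac,
                 wolbachia_effect = wolbachia_effect,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate a balanced expression study with known ground truth
#'
#' Each transcript's log2 value is baseline + fixed sex/treatment/Wolbachia
#' effects + random line-level draws at the design standard deviations +
#' residual noise. Every draw is recorded in the returned ground truth, so
#' recovery tests can compare estimates to the realized effects, not only to
#' their generating parameters.
#'
#' @param design a [sim_design()].
#' @return list with elements `study` (an [expression_study()], log2 scale)
#'   and `truth` (lists of realized draws, the LxT transcript set and the
#'   true per-transcript variance components).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  L <- design$n_lines; P <- design$n_transcripts; r <- design$n_replicates
  lines <- sprintf("line_%03d", seq_len(L))
  transcripts <- sprintf("TX%05d", seq_len(P))
  sexes <- c("F", "M"); treatments <- c("control", "ethanol")

  samples <- expand.grid(replicate = seq_len(r), treatment = treatments,
                         sex = sexes, line = lines,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("line", "sex", "treatment", "replicate")]
  wolb_lines <- sample(lines, round(design$wolbachia_frac * L))
  samples$wolbachia <- ifelse(samples$line %in% wolb_lines, "yes", "no")
  samples$sample <- sprintf("%s_%s_%s_r%d", samples$line, samples$sex,
                            substr(samples$treatment, 1, 3), samples$replicate)
  samples <- samples[, c("sample", "line", "sex", "treatment", "replicate",
                         "wolbachia")]
  n <- nrow(samples)

  baseline <- runif(P, 3, 9)
  n_lxt <- round(design$frac_lxt * P)
  lxt_tx <- if (n_lxt > 0) sort(sample(transcripts, n_lxt)) else character(0)
  sd_tl <- ifelse(transcripts %in% lxt_tx, design$sd_treatline, 0)

  ## random draws, one per transcript x grouping cell
  line_eff <- matrix(rnorm(P * L, 0, design$sd_line), P, L,
                     dimnames = list(transcripts, lines))
  sexline_eff <- array(rnorm(P * L * 2, 0, design$sd_sexline), c(P, L, 2),
                       dimnames = list(transcripts, lines, sexes))
  treatline_eff <- array(rnorm(P * L * 2), c(P, L, 2),
                         dimnames = list(transcripts, lines, treatments))
  treatline_eff <- treatline_eff * sd_tl
  sextreatline_eff <- array(rnorm(P * L * 4, 0, design$sd_sextreatline),
                            c(P, L, 2, 2),
                            dimnames = list(transcripts, lines, sexes,
                                            treatments))

  li <- match(samples$line, lines)
  si <- match(samples$sex, sexes)
  ti <- match(samples$treatment, treatments)
  Y <- matrix(baseline, P, n) +
    matrix(design$sex_effect * (samples$sex == "M"), P, n, byrow = TRUE) +
    matrix(design$treatment_effect * (samples$treatment == "ethanol"),
           P, n, byrow = TRUE) +
    matrix(design$wolbachia_effect * (samples$wolbachia == "yes"),
           P, n, byrow = TRUE) +
    line_eff[, li] +
    sexline_eff[cbind(rep(seq_len(P), n), rep(li, each = P),
                      rep(si, each = P))] +
    treatline_eff[cbind(rep(seq_len(P), n), rep(li, each = P),
                        rep(ti, each = P))] +
    sextreatline_eff[cbind(rep(seq_len(P), n), rep(li, each = P),
                           rep(si, each = P), rep(ti, each = P))] +
    matrix(rnorm(P * n, 0, design$sd_resid), P, n)
  dim(Y) <- c(P, n)
  dimnames(Y) <- list(transcripts, samples$sample)

  vc_true <- data.frame(
    transcript = transcripts,
    var_line = design$sd_line^2,
    var_sexline = design$sd_sexline^2,
    var_treatline = sd_tl^2,
    var_sextreatline = design$sd_sextreatline^2,
    var_resid = design$sd_resid^2)

  truth <- list(lxt_transcripts = lxt_tx,
                baseline = setNames(baseline, transcripts),
                line_effects = line_eff,
                sexline_effects = sexline_eff,
                treatline_effects = treatline_eff,
                sextreatline_effects = sextreatline_eff,
                wolbachia_lines = sort(wolb_lines),
                vc_true = vc_true,
                planted_modules = list(),
                planted_eqtls = NULL)
  list(study = expression_study(Y, samples, scale = "log2"), truth = truth)
}

#' Export a log2 study on the count scale
#'
#' Inverts the log2 model (2^Y), multiplies by a per-sample library-size
#' factor and rounds to integers, for exercising normalization.
#'
#' @param study log2-scale `expression_study`.
#' @param libsize_factor per-sample multiplier (recycled).
#' @return an `expression_study` on the counts scale.
#' @export
as_count_study <- function(study, libsize_factor = 1) {
  stopifnot(study$scale == "log2")
  counts <- round(t(t(2^study$values) *
                      rep_len(libsize_factor, ncol(study$values))))
  expression_study(counts, study$samples, scale = "counts")
}

#' Simulate homozygous inbred-line genotypes
#'
#' Lines x variants matrix coded 0/2 (fully inbred, biallelic), with
#' per-variant minor allele frequency drawn uniformly inside `maf_range` and
#' positions uniform over the supplied genome. The number of carrier lines is
#' `round(maf * n_lines)`, clamped to keep every variant polymorphic.
#'
#' @param n_lines number of lines (>= 2).
#' @param n_variants number of variants.
#' @param maf_range length-2 interval inside (0, 0.5].
#' @param genome data.frame with columns `chrom` and `length` (bp).
#' @param seed integer seed.
#' @return list of class `genotype_matrix` with elements `geno` (lines x
#'   variants, 0/2) and `variants` (variant, chrom, pos; 1-based).
#' @export
simulate_genotypes <- function(n_lines, n_variants,
                               maf_range = c(0.05, 0.5),
                               genome = data.frame(
                                 chrom = c("2L", "2R", "3L", "3R", "X"),
                                 length = c(23e6, 25e6, 28e6, 32e6, 23e6)),
                               seed = 1L) {
  if (n_lines < 2) stop("n_lines must be >= 2")
  if (any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie inside (0, 0.5]")
  set.seed(seed)
  lines <- sprintf("line_%03d", seq_len(n_lines))
  maf <- runif(n_variants, maf_range[1], maf_range[2])
  carriers <- pmin(pmax(round(maf * n_lines), 1L), n_lines - 1L)
  geno <- matrix(0L, n_lines, n_variants,
                 dimnames = list(lines, sprintf("VAR%05d", seq_len(n_variants))))
  for (j in seq_len(n_variants))
    geno[sample.int(n_lines, carriers[j]), j] <- 2L
  ci <- sample.int(nrow(genome), n_variants, replace = TRUE,
                   prob = genome$length)
  pos <- 1L + floor(runif(n_variants) * genome$length[ci])
  variants <- data.frame(variant = colnames(geno),
                         chrom = genome$chrom[ci], pos = as.integer(pos))
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]; rownames(variants) <- NULL
  geno <- geno[, variants$variant, drop = FALSE]
  structure(list(geno = geno, variants = variants),
            class = "genotype_matrix")
}

#' Plant eQTL effects on the ethanol-condition means
#'
#' For each (transcript, variant, beta) triple, adds `beta * genotype/2` to
#' the transcript's ethanol-condition samples of each line, so the
#' (ethanol - control) delta-expression carries the genetic signal.
#'
#' @param study an `expression_study`.
#' @param geno a `genotype_matrix` whose lines match the study.
#' @param effects data.frame with columns `transcript`, `variant`, `beta`.
#' @return the modified `expression_study`.
#' @export
plant_eqtls <- function(study, geno, effects) {
  stopifnot(inherits(study, "expression_study"),
            inherits(geno, "genotype_matrix"))
  bad_tx <- setdiff(effects$transcript, rownames(study$values))
  bad_v <- setdiff(effects$variant, colnames(geno$geno))
  if (length(bad_tx) || length(bad_v))
    stop("unknown ids in planted effects: ",
         paste(c(bad_tx, bad_v), collapse = ", "))
  eth <- which(study$samples$treatment == "ethanol")
  li <- match(study$samples$line[eth], rownames(geno$geno))
  if (anyNA(li)) stop("study lines missing from genotype matrix")
  for (k in seq_len(nrow(effects))) {
    g <- geno$geno[li, effects$variant[k]] / 2
    study$values[effects$transcript[k], eth] <-
      study$values[effects$transcript[k], eth] + effects$beta[k] * g
  }
  study
}

#' Plant co-regulated transcript modules
#'
#' Adds `loading * f_line` to the ethanol-condition samples of every member
#' transcript, where `f_line` is a shared per-line standard normal latent
#' factor (one independent factor per module). This induces positive
#' delta-expression correlation within each module.
#'
#' @param study an `expression_study`.
#' @param modules list of lists with elements `transcripts` (character) and
#'   `loading` (numeric scalar).
#' @param allow_overlap if FALSE (default), overlapping member sets error.
#' @param seed optional seed for the latent factors.
#' @return the modified `expression_study`, with the realized latent factors
#'   attached as `attr(, "module_factors")` (lines x modules).
#' @export
plant_modules <- function(study, modules, allow_overlap = FALSE,
                          seed = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (!length(modules)) return(study)
  if (!is.null(seed)) set.seed(seed)
  members <- lapply(modules, `[[`, "transcripts")
  if (any(!lengths(members))) stop("module member sets must be nonempty")
  if (!allow_overlap && anyDuplicated(unlist(members)))
    stop("planted modules overlap and allow_overlap = FALSE")
  bad <- setdiff(unlist(members), rownames(study$values))
  if (length(bad)) stop("unknown transcripts: ", paste(bad, collapse = ", "))
  lines <- sort(unique(study$samples$line))
  fac <- matrix(rnorm(length(lines) * length(modules)), length(lines),
                dimnames = list(lines, paste0("module_", seq_along(modules))))
  eth <- which(study$samples$treatment == "ethanol")
  li <- match(study$samples$line[eth], lines)
  for (m in seq_along(modules)) {
    shift <- modules[[m]]$loading * fac[li, m]
    study$values[members[[m]], eth] <-
      study$values[members[[m]], eth, drop = FALSE] +
      matrix(shift, length(members[[m]]), length(eth), byrow = TRUE)
  }
  attr(study, "module_factors") <- fac
  study
}

#' Synthesize a gene annotation table for the simulated transcripts
#'
#' Places each transcript as a gene of the given span uniformly on the
#' genome (1-based inclusive coordinates), for cis/trans classification of
#' planted eQTLs.
#'
#' @param transcripts character vector of gene/transcript ids.
#' @param genome data.frame `chrom`, `length`.
#' @param span_range gene-body length range in bp.
#' @param seed integer seed.
#' @return data.frame gene, chrom, start, end.
#' @export
simulate_gene_annotation <- function(transcripts,
                                     genome = data.frame(
                                       chrom = c("2L", "2R", "3L", "3R", "X"),
                                       length = c(23e6, 25e6, 28e6, 32e6, 23e6)),
                                     span_range = c(500, 10000), seed = 1L) {
  set.seed(seed)
  n <- length(transcripts)
  ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  span <- floor(runif(n, span_range[1], span_range[2]))
  start <- 1L + floor(runif(n) * pmax(genome$length[ci] - span, 1))
  data.frame(gene = transcripts, chrom = genome$chrom[ci],
             start = as.integer(start), end = as.integer(start + span - 1))
}

#' Synthesize a known-interaction edge list
#'
#' Random undirected edges among the supplied genes, typed genetic or
#' physical, deduplicated on (unordered pair, type). Optionally guarantees a
#' set of hub genes each linked to >= `hub_links` of the `anchors`, to
#' exercise the connectivity filter of the interaction-network stage.
#'
#' @param genes character vector of gene ids.
#' @param n_edges number of random edges to draw.
#' @param anchors,hubs,hub_links optional planted hub structure.
#' @param seed integer seed.
#' @return data.frame geneA, geneB, type.
#' @export
simulate_interactions <- function(genes, n_edges = 200, anchors = NULL,
                                  hubs = NULL, hub_links = 5, seed = 1L) {
  set.seed(seed)
  a <- sample(genes, n_edges, replace = TRUE)
  b <- sample(genes, n_edges, replace = TRUE)
  keep <- a != b
  edges <- data.frame(geneA = a[keep], geneB = b[keep],
                      type = sample(c("genetic", "physical"), sum(keep),
                                    replace = TRUE))
  for (h in hubs) {
    targets <- sample(anchors, min(hub_links, length(anchors)))
    edges <- rbind(edges, data.frame(geneA = h, geneB = targets,
                                     type = "physical"))
  }
  key <- paste(pmin(edges$geneA, edges$geneB),
               pmax(edges$geneA, edges$geneB), edges$type)
  edges[!duplicated(key), ]
}

#' Synthesize a gene-to-GO annotation table
#'
#' Assigns each gene to `terms_per_gene` terms drawn from a fixed term pool;
#' optionally plants one coherent term covering a given gene set.
#'
#' @param genes character vector of gene ids.
#' @param n_terms size of the term pool.
#' @param terms_per_gene terms drawn per gene.
#' @param planted optional list(term =, genes =) coherent annotation.
#' @param seed integer seed.
#' @return data.frame gene, term.
#' @export
simulate_go_annotation <- function(genes, n_terms = 20, terms_per_gene = 2,
                                   planted = NULL, seed = 1L) {
  set.seed(seed)
  pool <- sprintf("GO:%07d", seq_len(n_terms))
  ann <- data.frame(
    gene = rep(genes, each = terms_per_gene),
    term = unlist(lapply(genes, function(g)
      sample(pool, terms_per_gene))))
  if (!is.null(planted))
    ann <- rbind(ann, data.frame(gene = planted$genes, term = planted$term))
  unique(ann)
}

#' Write genotype matrix, variant table and gene annotation to TSV
#' @param geno a `genotype_matrix`.
#' @param geno_file,variant_file output paths.
#' @export
write_genotypes <- function(geno, geno_file, variant_file) {
  df <- data.frame(line = rownames(geno$geno), geno$geno, check.names = FALSE)
  write_tsv_prov(df, geno_file, "gxetrans genotypes coded 0/2")
  write_tsv_prov(geno$variants, variant_file, "gxetrans variants, pos 1-based")
  invisible(c(geno_file, variant_file))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(geno_file, variant_file) {
  tab <- read_tsv_prov(geno_file)
  geno <- as.matrix(tab[, -1, drop = FALSE])
  rownames(geno) <- tab[[1]]
  storage.mode(geno) <- "integer"
  variants <- read_tsv_prov(variant_file)
  structure(list(geno = geno[, variants$variant, drop = FALSE],
                 variants = variants), class = "genotype_matrix")
}

#' Read homozygous biallelic genotypes from a VCF file
#'
#' Accepts biallelic sites with homozygous calls: 0/0 (or 0|0) maps to 0,
#' 1/1 to 2. Heterozygous or missing calls error (inbred-line panels are
#' expected to be fully homozygous after filtering).
#'
#' @param vcf_file path to an uncompressed VCF.
#' @return a `genotype_matrix` (lines = VCF samples).
#' @export
read_genotypes_vcf <- function(vcf_file) {
  vcf <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt == "0/0"] <- 0L
  code[gt == "1/1"] <- 2L
  if (anyNA(code))
    stop("VCF contains non-homozygous or missing genotype calls")
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  geno <- t(code)
  colnames(geno) <- ids
  variants <- data.frame(variant = ids, chrom = unname(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]))
  structure(list(geno = geno, variants = variants),
            class = "genotype_matrix")
}
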