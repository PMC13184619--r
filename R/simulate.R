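#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions for a miniature, fully ground-truthed
#' tumour/normal cohort: a small two-chromosome genome carrying
#' non-overlapping TE loci, multi-exon reference genes with planted open
#' reading frames, and TE-initiated chimeric transcripts whose true TSS
#' lies inside a TE and carries a promoter motif (TATA element 30 bp
#' upstream plus an initiator at the start site) written into the genome
#' sequence.
#'
#' Planted transcripts fall into two roles: the first
#' `n_tumour_specific` are tumour-specific (never expressed in normals;
#' expressed in tumours with a cancer-type preference,
#' `p_expr_typeA`/`p_expr_typeB`), the rest are null (expressed with the
#' same probability, `p_expr_tumour`/`p_expr_normal`, in both arms).
#' Expression is Bernoulli per sample, independent across samples.  The
#' transcript at `survival_index` carries a proportional-hazards survival
#' effect of size `hazard_ratio` for expressing tumour samples.
#'
#' @param genome_length total genome size in bp across `n_chroms`
#'   chromosomes (default 200 kb over 2).
#' @param n_chroms number of chromosomes.
#' @param n_te_loci TE loci to annotate; must be at least
#'   `n_planted_te_transcripts` (each planted transcript starts in its own
#'   TE; the remainder are intergenic decoys).
#' @param n_ref_genes reference genes (3 exons, annotated CDS).
#' @param n_planted_te_transcripts TE-initiated chimeric transcripts to
#'   plant (at most 2 per reference gene).
#' @param n_tumour,n_normal cohort arm sizes.
#' @param n_tumour_specific planted transcripts with tumour-restricted
#'   expression.
#' @param p_expr_tumour,p_expr_normal per-sample expression probability of
#'   null planted transcripts in each arm.
#' @param p_expr_typeA,p_expr_typeB expression probability of
#'   tumour-specific transcripts in the two tumour types (their mean is
#'   the overall tumour expression rate).
#' @param tss_jitter_sd SD (bp) of the rounded-Normal jitter applied to
#'   every assembled 5' end, emulating assembler TSS imprecision.
#' @param coverage_depth mean per-base read depth over expressed exons.
#' @param coverage_sdlog lognormal spread (sdlog) of per-transcript,
#'   per-sample depth around `coverage_depth`, emulating the wide dynamic
#'   range of transcript expression; low-depth windows are genuinely
#'   harder for the TSS model, as low-expressed transcripts are in real
#'   data.
#' @param junction_mean,junction_dispersion negative-binomial mean and
#'   dispersion of per-intron junction read counts (`size` =
#'   1/dispersion); a drawn 0 leaves an assembled transcript without
#'   junction support, exercising the expressed-flag rule honestly.
#' @param cap_mass,cap_sigma total cap-label read mass placed at each true
#'   TSS and the SD (bp) of its Gaussian smoothing (0 = single base).
#' @param motif,inr promoter consensus strings written at TSS-30 and
#'   around the TSS (the initiator's third base is the start site).
#' @param survival_index index (among planted transcripts) of the one with
#'   a survival effect.
#' @param hazard_ratio hazard multiplier for tumours expressing the
#'   survival transcript.
#' @param base_hazard baseline exponential event rate (per day).
#' @param censor_upper administrative censoring horizon (days; censoring
#'   times uniform on (0, censor_upper]).
#' @param n_noise spurious multi-exon assemblies; half are degradation
#'   artifacts whose first exon sits inside an internal exon of a
#'   reference gene, half are TE-free intergenic noise.
#' @param p_noise per-sample presence probability of each noise assembly.
#' @param seed integer seed fixing every downstream draw.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000L, n_chroms = 2L,
                       n_te_loci = 30L, n_ref_genes = 10L,
                       n_planted_te_transcripts = 20L,
                       n_tumour = 100L, n_normal = 100L,
                       n_tumour_specific = 5L,
                       p_expr_tumour = 0.3, p_expr_normal = 0.3,
                       p_expr_typeA = 0.5, p_expr_typeB = 0.1,
                       tss_jitter_sd = 20, coverage_depth = 50,
                       coverage_sdlog = 1.2,
                       junction_mean = 10, junction_dispersion = 0.5,
                       cap_mass = 10, cap_sigma = 2,
                       motif = "TATAAATA", inr = "CCATTCG",
                       survival_index = 1L, hazard_ratio = 3,
                       base_hazard = 0.01, censor_upper = 150,
                       n_noise = 6L, p_noise = 0.2, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(p_expr_tumour, p_expr_normal, p_expr_typeA, p_expr_typeB, p_noise)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(genome_length, n_chroms, n_te_loci, n_ref_genes,
              n_planted_te_transcripts, n_tumour, n_normal)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (n_planted_te_transcripts > 2L * n_ref_genes)
    stop("at most 2 planted transcripts per reference gene: need >= ",
         ceiling(n_planted_te_transcripts / 2), " genes")
  if (n_te_loci < n_planted_te_transcripts)
    stop("need at least one TE locus per planted transcript")
  if (n_tumour_specific > n_planted_te_transcripts)
    stop("n_tumour_specific exceeds number of planted transcripts")
  if (survival_index > n_planted_te_transcripts)
    stop("survival_index exceeds number of planted transcripts")
  if (tss_jitter_sd < 0 || coverage_depth <= 0 || coverage_sdlog < 0 ||
      junction_mean <= 0 ||
      junction_dispersion <= 0 || hazard_ratio <= 0 || base_hazard <= 0)
    stop("rates and dispersions must be positive")
  structure(cfg, class = "sim_config")
}

# plant string S on `strand` at transcription-relative offset `off`
# (0 = TSS base, negative = upstream) into a per-chrom character vector
plant_string <- function(chars, tss, strand, off, S) {
  s <- strsplit(S, "")[[1]]
  if (strand == "+") {
    idx <- tss + off + seq_along(s)  # 1-based
  } else {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    s <- unname(comp[s])
    idx <- tss - off - seq_along(s) + 2L
  }
  ok <- idx >= 1 & idx <= length(chars)
  chars[idx[ok]] <- s[ok]
  chars
}

mirror_iv <- function(start, end, lo, hi) {
  # reflect a half-open interval within [lo, hi)
  c(start = lo + (hi - end), end = lo + (hi - start))
}

#' Simulate the reference layer: genome, TE annotation, gene catalogue
#'
#' Lays out `n_ref_genes` three-exon genes in sequential blocks along the
#' chromosomes (alternating strand), each with up to two upstream TE loci
#' hosting planted TE-initiated chimeric transcripts: first exon from a
#' TSS inside the TE to a novel splice donor, then the gene's second and
#' third exons.  Every true TSS (reference and planted) gets the promoter
#' motif and initiator written into the genome; every reference CDS is
#' recoded into a genuine ATG...stop open reading frame.  Remaining TE
#' loci are placed intergenically; noise-assembly templates (degradation
#' artifacts and TE-free intergenic transcripts) are also laid out here so
#' that the cohort step only draws per-sample randomness.
#'
#' @param config a [sim_config()].
#' @return object of class `te_reference`: list with `genome`
#'   (`DNAStringSet`), `chrom_sizes`, `te` (annotation `data.frame`),
#'   `ref_transcripts`, `planted` (ground-truth manifest `data.frame`),
#'   `planted_transcripts`, `noise_transcripts`, `noise_role`, `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chroms <- config$n_chroms
  clen <- as.integer(config$genome_length %/% n_chroms)
  chrom_sizes <- stats::setNames(rep(clen, n_chroms), paste0("chr", seq_len(n_chroms)))

  unit <- 11000L; gap <- 1000L
  n_genes <- config$n_ref_genes
  capacity <- sum(chrom_sizes %/% (unit + gap))
  if (capacity < n_genes)
    stop("genome too short: need at least ",
         format(n_genes * (unit + gap) + 20000L, big.mark = ","),
         " bp for ", n_genes, " gene blocks")

  chars <- lapply(chrom_sizes, function(n)
    sample(c("A", "C", "G", "T"), n, replace = TRUE))

  # -- block layout ----------------------------------------------------
  blocks <- data.frame(chrom = character(), u = integer(), strand = character(),
                       stringsAsFactors = FALSE)
  ch_i <- 1L; cursor <- 0L
  for (g in seq_len(n_genes)) {
    if (cursor + unit + gap > chrom_sizes[ch_i]) { ch_i <- ch_i + 1L; cursor <- 0L }
    if (ch_i > n_chroms) stop("genome too short for requested gene blocks")
    blocks <- rbind(blocks, data.frame(
      chrom = names(chrom_sizes)[ch_i], u = cursor,
      strand = if (g %% 2L == 1L) "+" else "-", stringsAsFactors = FALSE))
    cursor <- cursor + unit + gap
  }
  tail_chrom <- names(chrom_sizes)[n_chroms]
  tail_cursor <- if (ch_i == n_chroms) cursor else 0L

  te_families <- data.frame(
    family = c("L1HS", "L1PA2", "AluYa5", "AluSx", "LTR7", "MER20"),
    superfamily = c("L1", "L1", "Alu", "Alu", "ERV1", "hAT-Charlie"),
    te_class = c("LINE", "LINE", "SINE", "SINE", "LTR", "DNA"),
    kimura_mu = c(1, 4, 2, 12, 8, 25), stringsAsFactors = FALSE)

  te <- list(); ref_tx <- list(); planted_tx <- list(); planted <- list()
  n_planted <- config$n_planted_te_transcripts

  mk_te <- function(chrom, start, end, strand, i) {
    f <- te_families[(i - 1L) %% nrow(te_families) + 1L, ]
    data.frame(chrom = chrom, start = start, end = end, strand = strand,
               te_name = sprintf("TEloc_%03d", i), family = f$family,
               superfamily = f$superfamily, te_class = f$te_class,
               kimura = round(max(0, rnorm(1, f$kimura_mu, 0.5)), 3),
               stringsAsFactors = FALSE)
  }
  te_i <- 0L

  for (g in seq_len(n_genes)) {
    bl <- blocks[g, ]; u <- bl$u; s <- bl$strand; chrom <- bl$chrom
    # features in plus orientation relative to the unit, mirrored for '-'
    M <- function(st, en) {
      if (s == "+") c(start = u + st, end = u + en)
      else mirror_iv(u + st, u + en, u, u + unit)
    }
    e1len <- sample(300:700, 1)
    exon1 <- M(6000L, 6000L + e1len)
    exon2 <- M(8000L, 8300L)
    exon3 <- M(9500L, 10300L)
    exons <- data.frame(rbind(exon1, exon2, exon3))
    gene_id <- sprintf("gene_%02d", g)
    # CDS: starts 100 bp into exon1, ends in exon3 with total length % 3 == 0
    cds_len1 <- e1len - 100L
    rem <- (cds_len1 + 300L) %% 3L
    cds_len3 <- 450L + (3L - rem) %% 3L
    if (s == "+") {
      cds <- data.frame(start = c(exon1["start"] + 100L, exon2["start"], exon3["start"]),
                        end = c(exon1["end"], exon2["end"], exon3["start"] + cds_len3))
    } else {
      cds <- data.frame(start = c(exon1["start"], exon2["start"], exon3["end"] - cds_len3),
                        end = c(exon1["end"] - 100L, exon2["end"], exon3["end"]))
    }
    tx <- transcript_model(sprintf("ref_%02d", g), chrom, s, exons,
                           gene_id = gene_id, cds = cds)
    ref_tx[[g]] <- tx
    # promoter at the reference TSS
    tssr <- tss_position(tx)
    chars[[chrom]] <- plant_string(chars[[chrom]], tssr, s, -30L, config$motif)
    chars[[chrom]] <- plant_string(chars[[chrom]], tssr, s, -2L, config$inr)

    # planted TE transcripts (slots A at 2200, B at 200)
    for (slot in c("A", "B")) {
      idx <- (g - 1L) * 2L + if (slot == "A") 1L else 2L
      if (idx > n_planted) next
      off0 <- if (slot == "A") 2200L else 200L
      te_len <- sample(800:1500, 1)
      te_iv <- M(off0, off0 + te_len)
      te_i <- te_i + 1L
      te[[te_i]] <- mk_te(chrom, te_iv["start"], te_iv["end"], s, te_i)
      rel_tss <- off0 + sample(100:(te_len - 100L), 1)
      fe_len <- sample(250:600, 1)
      tss_iv <- M(rel_tss, rel_tss + 1L)            # the TSS base
      fe_iv <- M(rel_tss, rel_tss + fe_len)         # first exon
      tss_g <- if (s == "+") tss_iv["start"] else tss_iv["end"] - 1L
      pexons <- data.frame(rbind(fe_iv, exon2, exon3))
      ptx <- transcript_model(sprintf("planted_%02d", idx), chrom, s, pexons,
                              gene_id = gene_id)
      planted_tx[[idx]] <- ptx
      fe <- first_exon(ptx)
      chars[[chrom]] <- plant_string(chars[[chrom]], tss_g, s, -30L, config$motif)
      chars[[chrom]] <- plant_string(chars[[chrom]], tss_g, s, -2L, config$inr)
      planted[[idx]] <- data.frame(
        truth_id = sprintf("planted_%02d", idx), chrom = chrom, strand = s,
        true_tss = as.integer(tss_g), donor = fe$donor,
        te_name = te[[te_i]]$te_name, family = te[[te_i]]$family,
        gene_id = gene_id, stringsAsFactors = FALSE)
    }
  }

  # intergenic decoy TEs in the tail of the last chromosome
  n_extra <- config$n_te_loci - te_i
  for (k in seq_len(max(0L, n_extra))) {
    len <- sample(600:1200, 1)
    if (tail_cursor + len + 200L > chrom_sizes[tail_chrom])
      stop("genome too short to place ", n_extra, " decoy TE loci; ",
           "increase genome_length by ~", n_extra * 1500L, " bp")
    te_i <- te_i + 1L
    te[[te_i]] <- mk_te(tail_chrom, tail_cursor + 100L, tail_cursor + 100L + len,
                        sample(c("+", "-"), 1), te_i)
    tail_cursor <- tail_cursor + len + 200L
  }
  te <- do.call(rbind, te); rownames(te) <- NULL

  # noise-assembly templates
  noise_tx <- list(); noise_role <- character(0)
  n_noise <- config$n_noise
  n_deg <- n_noise %/% 2L
  for (k in seq_len(n_deg)) {
    g <- (k - 1L) %% n_genes + 1L
    gx <- ref_tx[[g]]
    ex <- gx$exons  # coordinate order; exon2 row depends on strand
    inner <- internal_exons(gx)[1, ]
    if (gx$strand == "+") {
      fe <- data.frame(start = inner$start + 150L, end = inner$end)
      dn <- gx$exons[3, ]
    } else {
      fe <- data.frame(start = inner$start, end = inner$end - 150L)
      dn <- gx$exons[1, ]
    }
    noise_tx[[k]] <- transcript_model(sprintf("noise_deg_%02d", k), gx$chrom,
                                      gx$strand, rbind(fe, dn))
    noise_role <- c(noise_role, "degradation")
  }
  for (k in seq_len(n_noise - n_deg)) {
    p <- tail_cursor + 200L
    if (p + 1300L > chrom_sizes[tail_chrom])
      stop("genome too short to place intergenic noise transcripts")
    noise_tx[[n_deg + k]] <- transcript_model(
      sprintf("noise_int_%02d", k), tail_chrom, sample(c("+", "-"), 1),
      data.frame(start = c(p, p + 800L), end = c(p + 300L, p + 1100L)))
    noise_role <- c(noise_role, "intergenic")
    tail_cursor <- tail_cursor + 1500L
  }

  genome <- Biostrings::DNAStringSet(vapply(chars, paste, character(1), collapse = ""))
  names(genome) <- names(chrom_sizes)

  # recode each reference CDS into a genuine ORF (ATG ... stop, no
  # internal stop), writing changed bases back through the exon chain
  for (g in seq_len(n_genes)) {
    tx <- ref_tx[[g]]
    cds_tx <- cds_transcript_coords(tx)
    seq <- as.character(spliced_sequence(tx, genome))
    cseq <- substr(seq, cds_tx[1] + 1L, cds_tx[2])
    codons <- substring(cseq, seq(1, nchar(cseq) - 2, 3), seq(3, nchar(cseq), 3))
    codons[1] <- "ATG"
    internal <- which(codons %in% c("TAA", "TAG", "TGA"))
    internal <- internal[internal < length(codons)]
    codons[internal] <- paste0("C", substr(codons[internal], 2, 3))
    codons[length(codons)] <- "TAA"
    newc <- paste(codons, collapse = "")
    changed <- which(strsplit(newc, "")[[1]] != strsplit(cseq, "")[[1]])
    if (length(changed)) {
      gpos <- transcript_to_genome(tx, cds_tx[1] + changed - 1L)
      base <- strsplit(newc, "")[[1]][changed]
      if (tx$strand == "-") {
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        base <- unname(comp[base])
      }
      chr <- as.character(genome[[tx$chrom]])
      for (j in seq_along(gpos))
        substr(chr, gpos[j] + 1L, gpos[j] + 1L) <- base[j]
      genome[[tx$chrom]] <- Biostrings::DNAString(chr)
    }
  }

  structure(list(genome = genome, chrom_sizes = chrom_sizes, te = te,
                 ref_transcripts = ref_tx,
                 planted = do.call(rbind, planted),
                 planted_transcripts = planted_tx,
                 noise_transcripts = noise_tx, noise_role = noise_role,
                 config = config),
            class = "te_reference")
}

# CDS of a transcript in spliced-transcript coordinates (0-based half-open)
cds_transcript_coords <- function(tx) {
  stopifnot(!is.null(tx$cds))
  widths <- tx$exons$end - tx$exons$start
  offs <- cumsum(c(0L, widths))
  topos <- function(g) {
    # genomic base g -> transcript offset
    i <- which(tx$exons$start <= g & g < tx$exons$end)
    stopifnot(length(i) == 1)
    if (tx$strand == "+") offs[i] + (g - tx$exons$start[i])
    else sum(widths) - 1L - (offs[i] + (g - tx$exons$start[i]))
  }
  gfirst <- if (tx$strand == "+") min(tx$cds$start) else max(tx$cds$end) - 1L
  glast <- if (tx$strand == "+") max(tx$cds$end) - 1L else min(tx$cds$start)
  c(topos(gfirst), topos(glast) + 1L)
}

# transcription-order intron list: data.frame(donor, acceptor)
intron_keys <- function(tx) {
  n <- n_exons(tx)
  if (n < 2) return(data.frame(donor = integer(0), acceptor = integer(0)))
  if (tx$strand == "+")
    data.frame(donor = tx$exons$end[-n], acceptor = tx$exons$start[-1])
  else
    data.frame(donor = rev(tx$exons$start[-1]), acceptor = rev(tx$exons$end[-n]))
}

#' Simulate a tumour/normal cohort over a simulated reference
#'
#' Draws, per sample: which planted/noise transcripts are present
#' (reference transcripts are expressed everywhere), assembler TSS jitter
#' on every 5' end, piecewise-constant coverage over expressed exons
#' (unique channel at full depth, multi channel at 30%), negative-binomial
#' junction read counts per intron, cap-label mass at every expressed
#' transcript's TRUE TSS, and survival times (tumour arm) exponential with
#' the hazard scaled by `hazard_ratio` when the designated transcript is
#' expressed.
#'
#' @param config a [sim_config()] (the same one passed to
#'   [simulate_reference()]).
#' @param reference a `te_reference` from [simulate_reference()].
#' @return object of class `te_cohort`: list with `samples` (named list;
#'   each has `transcripts`, `coverage` (sparse two-channel), `cap`
#'   (sparse), `junctions`, `total_mapped_reads`), `cohort` (metadata
#'   `data.frame`), `manifest` (list: `planted`, `expression` logical
#'   matrix, `junction_truth` count matrix, `origins`), `chrom_sizes`,
#'   `config`.
#' @export
simulate_cohort <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "te_reference"))
  set.seed(config$seed + 1L)
  csz <- reference$chrom_sizes
  n_pl <- config$n_planted_te_transcripts
  planted <- reference$planted

  samples_df <- data.frame(
    sample_id = c(sprintf("tumour_%03d", seq_len(config$n_tumour)),
                  sprintf("normal_%03d", seq_len(config$n_normal))),
    condition = c(rep("tumour", config$n_tumour), rep("normal", config$n_normal)),
    cancer_type = c(rep(c("typeA", "typeB"), length.out = config$n_tumour),
                    rep("none", config$n_normal)),
    tissue = "generic",
    stringsAsFactors = FALSE)
  samples_df$stage <- NA_character_
  tum <- samples_df$condition == "tumour"
  samples_df$stage[tum] <- sample(c("I", "II", "III"), sum(tum), replace = TRUE)

  role <- ifelse(seq_len(n_pl) <= config$n_tumour_specific, "tumour_specific", "null")
  p_expr <- function(i, cond, ctype) {
    if (role[i] == "tumour_specific") {
      if (cond != "tumour") 0
      else if (ctype == "typeA") config$p_expr_typeA else config$p_expr_typeB
    } else {
      if (cond == "tumour") config$p_expr_tumour else config$p_expr_normal
    }
  }

  n_s <- nrow(samples_df)
  expr <- matrix(FALSE, n_pl, n_s,
                 dimnames = list(planted$truth_id, samples_df$sample_id))
  for (i in seq_len(n_pl))
    for (s in seq_len(n_s))
      expr[i, s] <- runif(1) < p_expr(i, samples_df$condition[s],
                                      samples_df$cancer_type[s])

  jtruth <- matrix(NA_integer_, n_pl, n_s,
                   dimnames = list(planted$truth_id, samples_df$sample_id))
  nb_size <- 1 / config$junction_dispersion

  # Gaussian cap kernel
  cap_kernel <- local({
    if (config$cap_sigma <= 0) data.frame(off = 0L, w = 1)
    else {
      off <- seq(-3L * ceiling(config$cap_sigma), 3L * ceiling(config$cap_sigma))
      w <- exp(-off^2 / (2 * config$cap_sigma^2)); w <- w / sum(w)
      data.frame(off = off, w = w)
    }
  })

  jitter_tx <- function(tx, sd) {
    # move the 5' end of the first exon by rounded Normal(0, sd), keeping
    # the first exon at least 50 bp long and inside the chromosome
    if (sd <= 0) return(tx)
    d <- as.integer(round(rnorm(1, 0, sd)))
    ex <- tx$exons
    if (tx$strand == "+") {
      ns <- min(max(ex$start[1] + d, 0L), ex$end[1] - 50L)
      ex$start[1] <- ns
    } else {
      n <- nrow(ex)
      ne <- max(min(ex$end[n] + d, csz[[tx$chrom]]), ex$start[n] + 50L)
      ex$end[n] <- ne
    }
    tx$exons <- ex
    tx
  }

  origins <- list(); samples <- vector("list", n_s)
  names(samples) <- samples_df$sample_id
  for (s in seq_len(n_s)) {
    sid <- samples_df$sample_id[s]
    present <- c(reference$ref_transcripts,
                 reference$planted_transcripts[expr[, s]],
                 reference$noise_transcripts[runif(length(reference$noise_transcripts)) <
                                               config$p_noise])
    cov_rows <- list(); cap_rows <- list(); jn_rows <- list(); txs <- list()
    for (k in seq_along(present)) {
      base_tx <- present[[k]]
      tx <- jitter_tx(base_tx, config$tss_jitter_sd)
      tid <- sprintf("STRG.%d", k)
      tx$transcript_id <- tid
      tx$gene_id <- NA_character_   # assemblers do not know genes
      tx$sample_id <- sid
      tx$cds <- NULL
      txs[[k]] <- tx
      origins[[length(origins) + 1L]] <- data.frame(
        sample_id = sid, transcript_id = tid, origin = base_tx$transcript_id,
        stringsAsFactors = FALSE)
      is_noise <- grepl("^noise", base_tx$transcript_id)
      mean_depth <- if (is_noise) 10 else config$coverage_depth
      depth <- max(0.5, rlnorm(1, log(mean_depth) - config$coverage_sdlog^2 / 2,
                               config$coverage_sdlog))
      cov_rows[[k]] <- data.frame(chrom = tx$chrom, start = tx$exons$start,
                                  end = tx$exons$end, value = round(depth, 2),
                                  stringsAsFactors = FALSE)
      # cap mass at the TRUE (pre-jitter) TSS, except for noise assemblies
      if (!is_noise) {
        p0 <- tss_position(base_tx)
        pos <- p0 + cap_kernel$off
        ok <- pos >= 0 & pos < csz[[tx$chrom]]
        cap_rows[[k]] <- data.frame(chrom = tx$chrom, start = pos[ok],
                                    end = pos[ok] + 1L,
                                    value = config$cap_mass * cap_kernel$w[ok],
                                    stringsAsFactors = FALSE)
      }
      ik <- intron_keys(tx)
      if (nrow(ik)) {
        cnt <- rnbinom(nrow(ik), mu = config$junction_mean, size = nb_size)
        jn_rows[[k]] <- data.frame(chrom = tx$chrom, donor = ik$donor,
                                   acceptor = ik$acceptor, strand = tx$strand,
                                   count = cnt, stringsAsFactors = FALSE)
        pl_i <- match(base_tx$transcript_id, planted$truth_id)
        if (!is.na(pl_i)) jtruth[pl_i, s] <- cnt[1]
      }
    }
    jn <- do.call(rbind, jn_rows)
    jn <- stats::aggregate(count ~ chrom + donor + acceptor + strand, jn, sum)
    cov <- do.call(rbind, cov_rows)
    multi <- cov; multi$value <- round(multi$value * 0.3, 2)
    samples[[s]] <- list(
      transcripts = txs,
      coverage = sparse_coverage(csz, unique = cov, multi = multi),
      cap = do.call(rbind, cap_rows),
      junctions = jn[order(jn$chrom, jn$donor, jn$acceptor), ],
      total_mapped_reads = 100000L + as.integer(round(runif(1) * 100000)))
  }

  # survival (tumour arm only)
  surv_expr <- expr[config$survival_index, ]
  samples_df$survival_time <- NA_real_; samples_df$event <- NA_integer_
  for (s in which(tum)) {
    rate <- config$base_hazard * if (surv_expr[s]) config$hazard_ratio else 1
    t_ev <- rexp(1, rate)
    t_cn <- runif(1, 0, config$censor_upper)
    samples_df$survival_time[s] <- round(min(t_ev, t_cn), 2)
    samples_df$event[s] <- as.integer(t_ev <= t_cn)
  }

  manifest <- list(planted = cbind(planted, role = role,
                                   stringsAsFactors = FALSE),
                   expression = expr, junction_truth = jtruth,
                   origins = do.call(rbind, origins))
  structure(list(samples = samples, cohort = samples_df, manifest = manifest,
                 chrom_sizes = csz, config = config),
            class = "te_cohort")
}

#' Two-channel sparse coverage container
#'
#' Piecewise-constant coverage stored as bedGraph-style records;
#' overlapping records sum.  [coverage_window()] densifies any slice.
#'
#' @param chrom_sizes named integer vector.
#' @param unique,multi `data.frame`s with `chrom`, `start`, `end`, `value`.
#' @return object of class `sparse_coverage`.
#' @export
sparse_coverage <- function(chrom_sizes, unique, multi) {
  structure(list(chrom_sizes = chrom_sizes, unique = unique, multi = multi),
            class = "sparse_coverage")
}

#' Dense slice of one coverage channel over a window
#'
#' Positions outside the chromosome are zero-padded, so the result always
#' has `end - start` values.
#'
#' @param cov a `sparse_coverage`, a `coverage_track` (dense, from
#'   [read_coverage()]), or a bedGraph-style `data.frame` (e.g. cap
#'   labels).
#' @param chrom,start,end window (0-based half-open; may extend past the
#'   chromosome).
#' @param channel `"unique"` or `"multi"` (ignored for plain
#'   `data.frame`s).
#' @return numeric vector of length `end - start`.
#' @export
coverage_window <- function(cov, chrom, start, end, channel = "unique") {
  w <- end - start
  out <- numeric(w)
  add_rows <- function(d) {
    d <- d[d$chrom == chrom & d$end > start & d$start < end, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      a <- max(d$start[i], start) - start + 1L
      b <- min(d$end[i], end) - start
      out[a:b] <<- out[a:b] + d$value[i]
    }
  }
  if (inherits(cov, "sparse_coverage")) {
    add_rows(cov[[channel]])
  } else if (inherits(cov, "coverage_track")) {
    if (chrom %in% names(cov)) {
      v <- cov[[chrom]][[channel]]
      a <- max(start, 0L); b <- min(end, length(v))
      if (b > a) out[(a - start + 1L):(b - start)] <- v[(a + 1L):b]
    }
  } else if (is.data.frame(cov)) {
    add_rows(cov)
  } else stop("unsupported coverage container")
  out
}

#' Write the simulated reference layer to a directory
#'
#' Emits `genome.fa`, `te.bed`, `reference.gtf` — the exact formats the
#' pipeline consumes.
#'
#' @param reference a `te_reference`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(reference$genome, file.path(dir, "genome.fa"),
                              width = 80L)
  write_bed_te(reference$te, file.path(dir, "te.bed"))
  write_gtf(reference$ref_transcripts, file.path(dir, "reference.gtf"))
  invisible(dir)
}

#' Write a simulated cohort to a directory
#'
#' Per sample: `<id>.gtf`, `<id>.unique.bedgraph`, `<id>.multi.bedgraph`,
#' `<id>.cap.bedgraph`, `<id>.junctions.tsv`; plus `cohort.tsv`,
#' `totals.tsv`, and the ground-truth manifest
#' (`manifest_planted.tsv`, `manifest_expression.tsv`).
#'
#' @param cohort a `te_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sparse_to_dense <- function(d, csz) {
    out <- lapply(csz, numeric)
    for (ch in unique(d$chrom))
      out[[ch]] <- coverage_window(d[d$chrom == ch, ], ch, 0L, csz[[ch]])
    out
  }
  for (sid in names(cohort$samples)) {
    sm <- cohort$samples[[sid]]
    write_gtf(sm$transcripts, file.path(dir, paste0(sid, ".gtf")))
    write_bedgraph(sparse_to_dense(sm$coverage$unique, cohort$chrom_sizes),
                   file.path(dir, paste0(sid, ".unique.bedgraph")))
    write_bedgraph(sparse_to_dense(sm$coverage$multi, cohort$chrom_sizes),
                   file.path(dir, paste0(sid, ".multi.bedgraph")))
    write_bedgraph(sparse_to_dense(sm$cap, cohort$chrom_sizes),
                   file.path(dir, paste0(sid, ".cap.bedgraph")))
    write_junctions(sm$junctions, file.path(dir, paste0(sid, ".junctions.tsv")))
  }
  write_cohort_table <- cohort$cohort
  write.table(write_cohort_table, file.path(dir, "cohort.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  totals <- data.frame(sample_id = names(cohort$samples),
                       total_mapped_reads = vapply(cohort$samples,
                                                   `[[`, numeric(1),
                                                   "total_mapped_reads"))
  write.table(totals, file.path(dir, "totals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$manifest$planted, file.path(dir, "manifest_planted.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  em <- data.frame(truth_id = rownames(cohort$manifest$expression),
                   cohort$manifest$expression, check.names = FALSE)
  write.table(em, file.path(dir, "manifest_expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
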