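#' Simulation configuration for a synthetic MA cohort
#'
#' Defaults emulate, at desk scale, a selfed diploid MA cohort: four
#' treatment groups of 40 lines on a 1 Mb / 5-contig reference at 36% GC,
#' shared germline variants plus line-private de novo mutations whose
#' per-line expectations match the cohort the analysis targets (about 4.2
#' SNVs and 0.5 InDels per line with a diploid site factor of 2), 17%
#' homozygous singletons, a transition-biased spectrum, InDel sizes 1-28 bp
#' with 77% of mass on 1-3 bp, a deletion excess (insertion:deletion 0.45),
#' and half of the InDels placed adjacent to planted homopolymer or tandem-
#' repeat tracts.
#'
#' @param genome_length Total reference length in bp.
#' @param n_contigs Number of contigs (lengths split evenly).
#' @param gc_fraction GC content of the i.i.d. background sequence.
#' @param groups Treatment labels (must not contain `"-"`).
#' @param n_lines_per_group Lines per group.
#' @param germline_variant_count Shared (pre-existing) variants to plant;
#'   each is carried by at least two lines.
#' @param snv_rate,indel_rate Heritable de novo rates per site per line per
#'   generation, on the zygosity-weighted scale the rate estimator reports
#'   (a heterozygous observation contributes 1/2). The expected number of
#'   *observed* mutations planted per line is therefore
#'   `rate * D * S * g * 2 / (1 + hom_fraction)`.
#' @param generations Number of selfed generations.
#' @param diploid_factor Mutational-target multiplier D (2 = both homologs).
#' @param hom_fraction Probability a de novo mutation is homozygous.
#' @param transition_fraction Share of de novo SNVs that are transitions
#'   (used to build `substitution_weights` when that is NULL).
#' @param substitution_weights Optional named probability vector over
#'   [SUBSTITUTION_CLASSES].
#' @param indel_len_distribution Optional probability vector over sizes
#'   1-28 bp.
#' @param ins_del_ratio Expected insertions per deletion.
#' @param repeat_adjacent_fraction Share of de novo InDels planted as
#'   expansions/contractions of repeat tracts.
#' @param repeat_density Planted repeat tracts per bp (default 1 per 5 kb).
#' @param context_motif Optional `list(motif=, strength=, bases=)`: rewrite
#'   the -3..-1 upstream reference bases of a planted SNV at a base in
#'   `bases` with `motif`, with probability `strength`.
#' @param germline_share_prob Binomial sharing parameter: a germline variant
#'   is carried by `2 + Binom(n_lines - 2, p)` lines.
#' @param germline_hom_fraction Probability a germline carrier is
#'   homozygous.
#' @param missing_fraction Fraction of genotype cells masked to missing.
#' @param min_separation Minimum bp between planted variant positions.
#' @param seed Integer seed (NULL leaves the RNG state alone).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6,
                       n_contigs = 5,
                       gc_fraction = 0.36,
                       groups = c("CK", "M24.5", "M30.5", "M33"),
                       n_lines_per_group = 40,
                       germline_variant_count = 1500,
                       snv_rate = 1.1e-6,
                       indel_rate = 1.3e-7,
                       generations = 1,
                       diploid_factor = 2,
                       hom_fraction = 0.17,
                       transition_fraction = 0.6,
                       substitution_weights = NULL,
                       indel_len_distribution = NULL,
                       ins_del_ratio = 0.45,
                       repeat_adjacent_fraction = 0.5,
                       repeat_density = 1 / 5000,
                       context_motif = NULL,
                       germline_share_prob = 0.25,
                       germline_hom_fraction = 0.5,
                       missing_fraction = 0,
                       min_separation = 32,
                       seed = NULL) {
  stopifnot(gc_fraction >= 0, gc_fraction <= 1,
            hom_fraction >= 0, hom_fraction <= 1,
            transition_fraction >= 0, transition_fraction <= 1,
            snv_rate >= 0, indel_rate >= 0, ins_del_ratio > 0,
            repeat_adjacent_fraction >= 0, repeat_adjacent_fraction <= 1,
            missing_fraction >= 0, missing_fraction < 1,
            generations >= 1, diploid_factor > 0)
  if (any(grepl("-", groups, fixed = TRUE)))
    stop("group labels must not contain '-'")
  if (is.null(substitution_weights)) {
    ti <- c("A>G", "G>A", "C>T", "T>C")
    w <- setNames(rep((1 - transition_fraction) / 8, 12),
                  SUBSTITUTION_CLASSES)
    w[ti] <- transition_fraction / 4
    substitution_weights <- w
  } else {
    if (length(substitution_weights) != 12 ||
        !setequal(names(substitution_weights), SUBSTITUTION_CLASSES))
      stop("substitution_weights must be named over the 12 classes")
    substitution_weights <- substitution_weights[SUBSTITUTION_CLASSES]
  }
  if (abs(sum(substitution_weights) - 1) > 1e-9)
    stop("substitution_weights must sum to 1")
  if (is.null(indel_len_distribution)) {
    short <- 0.5 ^ (0:2)
    long <- 0.75 ^ (0:24)
    indel_len_distribution <- c(0.7706 * short / sum(short),
                                (1 - 0.7706) * long / sum(long))
  }
  if (length(indel_len_distribution) != 28)
    stop("indel_len_distribution must cover sizes 1..28")
  if (abs(sum(indel_len_distribution) - 1) > 1e-9)
    stop("indel_len_distribution must sum to 1")
  if (!is.null(context_motif)) {
    stopifnot(is.list(context_motif), !is.null(context_motif$motif),
              nchar(context_motif$motif) == 3,
              context_motif$strength >= 0, context_motif$strength <= 1)
    context_motif$bases <- context_motif$bases %||% c("C", "G")
  }
  if (germline_variant_count > 0 &&
      germline_variant_count >= genome_length / 100)
    stop("germline_variant_count must be < genome_length / 100")
  structure(list(
    genome_length = genome_length, n_contigs = n_contigs,
    gc_fraction = gc_fraction, groups = groups,
    n_lines_per_group = n_lines_per_group,
    germline_variant_count = germline_variant_count,
    snv_rate = snv_rate, indel_rate = indel_rate,
    generations = generations, diploid_factor = diploid_factor,
    hom_fraction = hom_fraction, transition_fraction = transition_fraction,
    substitution_weights = substitution_weights,
    indel_len_distribution = indel_len_distribution,
    ins_del_ratio = ins_del_ratio,
    repeat_adjacent_fraction = repeat_adjacent_fraction,
    repeat_density = repeat_density, context_motif = context_motif,
    germline_share_prob = germline_share_prob,
    germline_hom_fraction = germline_hom_fraction,
    missing_fraction = missing_fraction,
    min_separation = min_separation, seed = seed),
    class = "sim_config")
}

#' Line identifiers of a simulated cohort
#' @param cfg A `sim_config`.
#' @return Named character vector line -> group label.
#' @export
sim_line_groups <- function(cfg) {
  lines <- unlist(lapply(cfg$groups, function(g)
    paste0(g, "_", sprintf("%02d", seq_len(cfg$n_lines_per_group)))))
  setNames(rep(cfg$groups, each = cfg$n_lines_per_group), lines)
}

.base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                              G = gc / 2, T = (1 - gc) / 2)

#' Simulate a reference genome with planted repeat tracts
#'
#' I.i.d. bases at the configured GC content, salted with homopolymer runs
#' (5-12 bp) and di/trinucleotide tandem repeats (3-6 copies) at
#' `repeat_density`, recorded in the `repeat_tracts` attribute so that
#' downstream InDel placement and adjacency tests have known positives.
#' Setting `cfg$seed` makes the genome reproducible.
#'
#' @param cfg A [sim_config()].
#' @return A [reference_genome()] with a `repeat_tracts` attribute
#'   (data.frame `contig`, `start`, `end`, `type`, `unit`, `copies`).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  probs <- .base_probs(cfg$gc_fraction)
  lens <- rep(floor(cfg$genome_length / cfg$n_contigs), cfg$n_contigs)
  lens[cfg$n_contigs] <- cfg$genome_length - sum(lens[-cfg$n_contigs])
  names(lens) <- paste0("chr", seq_len(cfg$n_contigs))
  contigs <- character(cfg$n_contigs)
  tracts <- list()
  for (i in seq_len(cfg$n_contigs)) {
    seq <- paste(sample(names(probs), lens[i], replace = TRUE, prob = probs),
                 collapse = "")
    n_tracts <- round(lens[i] * cfg$repeat_density)
    if (n_tracts > 0) {
      starts <- sort(sample.int(lens[i] - 60, n_tracts))
      starts <- starts[c(TRUE, diff(starts) > 60)]
      tr <- lapply(starts, function(st) {
        if (runif(1) < 0.5) {
          b <- sample(names(probs), 1, prob = probs)
          len <- sample(5:12, 1)
          list(start = st, end = st + len - 1, type = "homopolymer",
               unit = b, copies = len, str = strrep(b, len))
        } else {
          u <- sample(2:3, 1)
          repeat {
            unit <- paste(sample(names(probs), u, replace = TRUE,
                                 prob = probs), collapse = "")
            if (length(unique(strsplit(unit, "")[[1]])) > 1) break
          }
          copies <- sample(3:6, 1)
          list(start = st, end = st + u * copies - 1, type = "tandem",
               unit = unit, copies = copies,
               str = strrep(unit, copies))
        }
      })
      for (t in tr) substr(seq, t$start, t$end) <- t$str
      tracts[[i]] <- data.frame(
        contig = names(lens)[i],
        start = vapply(tr, `[[`, numeric(1), "start"),
        end = vapply(tr, `[[`, numeric(1), "end"),
        type = vapply(tr, `[[`, character(1), "type"),
        unit = vapply(tr, `[[`, character(1), "unit"),
        copies = vapply(tr, `[[`, numeric(1), "copies"))
    }
    contigs[i] <- seq
  }
  genome <- reference_genome(setNames(contigs, names(lens)))
  attr(genome, "repeat_tracts") <-
    if (length(tracts)) do.call(rbind, tracts) else
      data.frame(contig = character(), start = numeric(), end = numeric(),
                 type = character(), unit = character(), copies = numeric())
  genome
}

## Mutable per-contig registry of occupied positions, with a minimum
## separation between planted variants (keeps alleles, flanks and motif
## rewrites from overlapping each other).
.new_used <- function(contigs) {
  e <- new.env(parent = emptyenv())
  for (ct in contigs) assign(ct, numeric(0), envir = e)
  e
}
.is_free <- function(used, contig, pos, min_sep) {
  u <- get(contig, envir = used)
  length(u) == 0 || !any(abs(u - pos) < min_sep)
}
.occupy <- function(used, contig, pos) {
  assign(contig, c(get(contig, envir = used), pos), envir = used)
}

## Per-contig, per-base position pools; positions within `pad` of a planted
## repeat tract (or an N) are excluded so that randomly placed variants do
## not sit on tract boundaries.
.base_pools <- function(genome, pad = 4) {
  tracts <- attr(genome, "repeat_tracts")
  pools <- list()
  for (ct in names(genome$contigs)) {
    chars <- strsplit(genome$contigs[[ct]], "")[[1]]
    excl <- rep(FALSE, length(chars))
    tr <- tracts[tracts$contig == ct, , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      lo <- max(1, tr$start[i] - pad)
      hi <- min(length(chars), tr$end[i] + pad)
      excl[lo:hi] <- TRUE
    }
    pools[[ct]] <- lapply(setNames(c("A", "C", "G", "T"),
                                   c("A", "C", "G", "T")),
                          function(b) which(chars == b & !excl))
  }
  pools
}

## Draw one free position whose reference base is `base` (NULL = any base),
## respecting the separation registry. Returns list(contig, pos).
.draw_position <- function(pools, used, min_sep, base = NULL,
                           max_tries = 1000) {
  sizes <- vapply(pools, function(p) {
    if (is.null(base)) sum(lengths(p)) else length(p[[base]])
  }, numeric(1))
  if (sum(sizes) == 0) stop("no available positions",
                            if (!is.null(base)) paste0(" with base ", base))
  for (i in seq_len(max_tries)) {
    ct <- sample(names(sizes), 1, prob = sizes)
    b <- if (is.null(base)) {
      bl <- lengths(pools[[ct]])
      sample(names(bl), 1, prob = bl)
    } else base
    p <- pools[[ct]][[b]]
    pos <- p[sample.int(length(p), 1)]
    if (.is_free(used, ct, pos, min_sep)) {
      .occupy(used, ct, pos)
      return(list(contig = ct, pos = pos))
    }
  }
  stop("could not place variant after ", max_tries,
       " tries; genome too densely planted")
}

#' Plant shared germline variants
#'
#' Plants `cfg$germline_variant_count` SNVs, each carried by at least two
#' lines (`2 + Binom(n_lines - 2, germline_share_prob)` carriers), so the
#' singleton filter must remove every one of them.
#'
#' @param genome A simulated `reference_genome`.
#' @param cfg A `sim_config`.
#' @param used Internal position registry (created when NULL).
#' @param pools Internal base-position pools (computed when NULL).
#' @return List with `variants` (data.frame `variant_id`, `contig`, `pos`,
#'   `ref`, `alt`) and `carriers` (data.frame `variant_id`, `line`,
#'   `genotype`).
#' @export
plant_germline_variants <- function(genome, cfg, used = NULL, pools = NULL) {
  stopifnot(inherits(genome, "reference_genome"), inherits(cfg, "sim_config"))
  lines <- names(sim_line_groups(cfg))
  if (is.null(used)) used <- .new_used(names(genome$contigs))
  if (is.null(pools)) pools <- .base_pools(genome)
  n <- cfg$germline_variant_count
  if (n == 0)
    return(list(variants = data.frame(variant_id = character(),
                                      contig = character(), pos = integer(),
                                      ref = character(), alt = character()),
                carriers = data.frame(variant_id = character(),
                                      line = character(),
                                      genotype = character())))
  bases <- c("A", "C", "G", "T")
  vars <- vector("list", n)
  carrs <- vector("list", n)
  for (i in seq_len(n)) {
    at <- .draw_position(pools, used, cfg$min_separation)
    ref <- get_seq(genome, at$contig, at$pos)
    alt <- sample(setdiff(bases, ref), 1)
    vid <- paste0("g", i)
    k <- 2 + rbinom(1, length(lines) - 2, cfg$germline_share_prob)
    who <- sample(lines, k)
    gt <- ifelse(runif(k) < cfg$germline_hom_fraction, "hom_alt", "het")
    vars[[i]] <- data.frame(variant_id = vid, contig = at$contig,
                            pos = at$pos, ref = ref, alt = alt)
    carrs[[i]] <- data.frame(variant_id = vid, line = who, genotype = gt)
  }
  list(variants = do.call(rbind, vars), carriers = do.call(rbind, carrs))
}

#' Plant line-private de novo mutations
#'
#' Per line, the observed SNV and InDel counts are Poisson with mean
#' `rate * D * non_n_length * generations * 2 / (1 + hom_fraction)`: the
#' configured rates are heritable (zygosity-weighted) rates, so the
#' expected value of `N_hom + N_het / 2` equals `rate * D * S * g` per line
#' and the downstream estimator is unbiased for them. SNV positions are drawn
#' uniformly over sites carrying the reference base demanded by the
#' substitution class (classes drawn from `substitution_weights`); zygosity
#' is Bernoulli(`hom_fraction`). InDel sizes follow
#' `indel_len_distribution`, direction follows `ins_del_ratio`, and a
#' `repeat_adjacent_fraction` share is planted as expansions or contractions
#' of the reference's planted repeat tracts (tract type chosen compatible
#' with the drawn size, so sizes are preserved; contractions are clamped to
#' keep part of the tract in place). When `cfg$context_motif` is set, the
#' -3..-1 upstream reference bases of qualifying SNV sites are rewritten
#' with the motif, with probability `strength`; the returned genome carries
#' these rewrites.
#'
#' @inheritParams plant_germline_variants
#' @return List with `genome` (possibly motif-rewritten) and `denovo`
#'   (data.frame `line`, `contig`, `pos`, `ref`, `alt`, `vtype`, `size`,
#'   `zygosity`, `class`, `planted_adjacent`, `motif_applied`).
#' @export
plant_denovo_mutations <- function(genome, cfg, used = NULL, pools = NULL) {
  stopifnot(inherits(genome, "reference_genome"), inherits(cfg, "sim_config"))
  lg <- sim_line_groups(cfg)
  if (is.null(used)) used <- .new_used(names(genome$contigs))
  if (is.null(pools)) pools <- .base_pools(genome)
  tracts <- attr(genome, "repeat_tracts")
  tract_free <- rep(TRUE, nrow(tracts))
  probs <- .base_probs(cfg$gc_fraction)
  D <- cfg$diploid_factor
  # observed-count scale: het observations carry 1/2 heritable weight
  target <- genome$non_n_length * D * cfg$generations *
    2 / (1 + cfg$hom_fraction)
  recs <- list()
  motif_sites <- list()

  for (ln in names(lg)) {
    n_snv <- rpois(1, cfg$snv_rate * target)
    n_ind <- rpois(1, cfg$indel_rate * target)
    if (n_snv > 0) {
      classes <- sample(SUBSTITUTION_CLASSES, n_snv, replace = TRUE,
                        prob = cfg$substitution_weights)
      for (cl in classes) {
        refb <- substring(cl, 1, 1)
        altb <- substring(cl, 3, 3)
        at <- .draw_position(pools, used, cfg$min_separation, base = refb)
        zyg <- if (runif(1) < cfg$hom_fraction) "homozygous" else
          "heterozygous"
        motif <- FALSE
        cm <- cfg$context_motif
        if (!is.null(cm) && refb %in% cm$bases && at$pos - 3 >= 1 &&
            runif(1) < cm$strength) {
          motif <- TRUE
          motif_sites[[length(motif_sites) + 1]] <-
            list(contig = at$contig, pos = at$pos)
        }
        recs[[length(recs) + 1]] <- data.frame(
          line = ln, contig = at$contig, pos = at$pos, ref = refb,
          alt = altb, vtype = "SNV", size = 0L, zygosity = zyg, class = cl,
          planted_adjacent = FALSE, motif_applied = motif)
      }
    }
    if (n_ind > 0) {
      for (j in seq_len(n_ind)) {
        size <- sample.int(28, 1, prob = cfg$indel_len_distribution)
        is_ins <- runif(1) < cfg$ins_del_ratio / (1 + cfg$ins_del_ratio)
        zyg <- if (runif(1) < cfg$hom_fraction) "homozygous" else
          "heterozygous"
        want_adj <- runif(1) < cfg$repeat_adjacent_fraction
        placed <- FALSE
        if (want_adj && nrow(tracts)) {
          compat <- which(tract_free &
                            (tracts$type == "homopolymer" |
                               size %% nchar(tracts$unit) == 0))
          for (ti in compat[sample.int(length(compat))]) {
            tr <- tracts[ti, ]
            u <- nchar(tr$unit)
            if (is_ins) {
              pos <- tr$end
              s_eff <- if (tr$type == "homopolymer") size else
                u * max(1, size %/% u)
              ins_seq <- if (tr$type == "homopolymer")
                strrep(tr$unit, s_eff) else strrep(tr$unit, s_eff / u)
              if (!.is_free(used, tr$contig, pos, cfg$min_separation)) next
              ref <- get_seq(genome, tr$contig, pos)
              alt <- paste0(ref, ins_seq)
            } else {
              span <- tr$end - tr$start + 1
              s_eff <- if (tr$type == "homopolymer")
                min(size, span - 1) else u * min(max(1, size %/% u),
                                                 tr$copies - 1)
              pos <- tr$end - s_eff
              if (pos < 1) next
              if (!.is_free(used, tr$contig, pos, cfg$min_separation)) next
              ref <- get_seq(genome, tr$contig, pos, tr$end)
              alt <- substring(ref, 1, 1)
            }
            .occupy(used, tr$contig, pos)
            tract_free[ti] <- FALSE
            recs[[length(recs) + 1]] <- data.frame(
              line = ln, contig = tr$contig, pos = pos, ref = ref,
              alt = alt, vtype = if (is_ins) "INS" else "DEL",
              size = s_eff, zygosity = zyg, class = NA_character_,
              planted_adjacent = TRUE, motif_applied = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          # random (not deliberately repeat-adjacent) placement
          repeat {
            at <- .draw_position(pools, used, cfg$min_separation)
            len_ct <- nchar(genome$contigs[[at$contig]])
            if (!is_ins && at$pos + size > len_ct) next
            break
          }
          if (is_ins) {
            ref <- get_seq(genome, at$contig, at$pos)
            alt <- paste0(ref, paste(
              sample(names(probs), size, replace = TRUE, prob = probs),
              collapse = ""))
          } else {
            ref <- get_seq(genome, at$contig, at$pos, at$pos + size)
            alt <- substring(ref, 1, 1)
          }
          recs[[length(recs) + 1]] <- data.frame(
            line = ln, contig = at$contig, pos = at$pos, ref = ref,
            alt = alt, vtype = if (is_ins) "INS" else "DEL",
            size = size, zygosity = zyg, class = NA_character_,
            planted_adjacent = FALSE, motif_applied = FALSE)
        }
      }
    }
  }
  denovo <- if (length(recs)) do.call(rbind, recs) else
    data.frame(line = character(), contig = character(), pos = integer(),
               ref = character(), alt = character(), vtype = character(),
               size = integer(), zygosity = character(), class = character(),
               planted_adjacent = logical(), motif_applied = logical())
  # apply motif rewrites, then refresh ref alleles from the final genome
  # (planted sites are separated by >= min_separation, so a rewrite can
  # only touch its own site's upstream flank)
  if (length(motif_sites)) {
    motif <- cfg$context_motif$motif
    for (ms in motif_sites)
      substr(genome$contigs[[ms$contig]], ms$pos - 3, ms$pos - 1) <- motif
  }
  if (nrow(denovo)) {
    for (i in seq_len(nrow(denovo))) {
      want <- get_seq(genome, denovo$contig[i], denovo$pos[i],
                      denovo$pos[i] + nchar(denovo$ref[i]) - 1)
      stopifnot(want == denovo$ref[i])  # alleles anchored on the reference
    }
  }
  list(genome = genome, denovo = denovo)
}

#' Simulate a full MA cohort
#'
#' Runs [simulate_reference()], [plant_germline_variants()] and
#' [plant_denovo_mutations()] under one seed and assembles the genotyped
#' [cohort_table()]. De novo variants are line-private by construction and
#' germline variants are never private, so the singleton stage has an exact
#' ground truth.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `ma_simulation`: `config`, `genome`, `truth`
#'   (list `germline`, `germline_carriers`, `denovo`), `cohort`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- simulate_reference(cfg)   # seeds the RNG when cfg$seed is set
  used <- .new_used(names(genome$contigs))
  pools <- .base_pools(genome)
  germ <- plant_germline_variants(genome, cfg, used, pools)
  dn <- plant_denovo_mutations(genome, cfg, used, pools)
  genome <- dn$genome
  lg <- sim_line_groups(cfg)

  loci <- rbind(
    data.frame(contig = germ$variants$contig, pos = germ$variants$pos,
               ref = germ$variants$ref, alt = germ$variants$alt,
               src = germ$variants$variant_id),
    data.frame(contig = dn$denovo$contig, pos = dn$denovo$pos,
               ref = dn$denovo$ref, alt = dn$denovo$alt,
               src = sprintf("d%d", seq_len(nrow(dn$denovo)))))
  gt <- matrix("hom_ref", nrow(loci), length(lg),
               dimnames = list(NULL, names(lg)))
  if (nrow(germ$carriers)) {
    row_of <- match(germ$carriers$variant_id, loci$src)
    gt[cbind(row_of, match(germ$carriers$line, names(lg)))] <-
      germ$carriers$genotype
  }
  if (nrow(dn$denovo)) {
    drows <- match(paste0("d", seq_len(nrow(dn$denovo))), loci$src)
    gt[cbind(drows, match(dn$denovo$line, names(lg)))] <-
      ifelse(dn$denovo$zygosity == "homozygous", "hom_alt", "het")
  }
  if (cfg$missing_fraction > 0) {
    mask <- runif(length(gt)) < cfg$missing_fraction
    gt[mask] <- "missing"
  }
  cohort <- sort_cohort(cohort_table(loci[, c("contig", "pos", "ref", "alt")],
                                     gt, lg))
  structure(list(config = cfg, genome = genome,
                 truth = list(germline = germ$variants,
                              germline_carriers = germ$carriers,
                              denovo = dn$denovo),
                 cohort = cohort),
            class = "ma_simulation")
}

#' @export
print.ma_simulation <- function(x, ...) {
  cat("ma_simulation:", nrow(x$truth$germline), "germline +",
      nrow(x$truth$denovo), "de novo planted variants;",
      ncol(x$cohort$genotypes), "lines\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `reference.fa`, `cohort.vcf` (joint multi-sample, anchor-base
#' form), `groups.tsv` and `truth.tsv` into `out_dir`. Re-running with the
#' same seed yields byte-identical files.
#'
#' @param sim An `ma_simulation`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
emit_cohort <- function(sim, out_dir) {
  stopifnot(inherits(sim, "ma_simulation"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(reference = file.path(out_dir, "reference.fa"),
             vcf = file.path(out_dir, "cohort.vcf"),
             groups = file.path(out_dir, "groups.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_reference(sim$genome, paths["reference"])
  write_cohort_vcf(sim$cohort, paths["vcf"], reference_name = "synthetic")
  lg <- sim$cohort$line_groups
  write.table(data.frame(line = names(lg), group = unname(lg)),
              paths["groups"], sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth$denovo
  truth <- rbind(
    data.frame(origin = character(), line = character(),
               contig = character(), pos = integer(), ref = character(),
               alt = character(), vtype = character(), size = integer(),
               zygosity = character(), planted_adjacent = logical()),
    if (nrow(sim$truth$germline))
      data.frame(origin = "germline", line = NA_character_,
                 sim$truth$germline[, c("contig", "pos", "ref", "alt")],
                 vtype = NA_character_, size = NA_integer_,
                 zygosity = NA_character_, planted_adjacent = NA),
    if (nrow(tr))
      data.frame(origin = "denovo", line = tr$line,
                 tr[, c("contig", "pos", "ref", "alt")],
                 vtype = tr$vtype, size = tr$size, zygosity = tr$zygosity,
                 planted_adjacent = tr$planted_adjacent))
  write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
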