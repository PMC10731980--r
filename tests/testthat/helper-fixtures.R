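# Shared fixture builders and independent brute-force oracles.

# Singleton set with a prescribed composition; positions/lines are synthetic.
make_singletons <- function(n_snv, n_ins = 0, n_del = 0, n_hom = 0,
                            n_lines = 4, groups = c("CK", "TX")) {
  n <- n_snv + n_ins + n_del
  lines <- paste0("L", seq_len(n_lines))
  lg <- setNames(rep(groups, length.out = n_lines), lines)
  vtype <- c(rep("SNV", n_snv), rep("INS", n_ins), rep("DEL", n_del))
  ref <- ifelse(vtype == "SNV", "C", ifelse(vtype == "INS", "A", "ACC"))
  alt <- ifelse(vtype == "SNV", "T", ifelse(vtype == "INS", "AGG", "A"))
  size <- ifelse(vtype == "SNV", 0L, 2L)
  zyg <- c(rep("homozygous", n_hom), rep("heterozygous", n - n_hom))
  df <- data.frame(contig = rep("chr1", n), pos = seq_len(n) * 100L,
                   ref = ref, alt = alt, vtype = vtype, size = size,
                   line = rep(lines, length.out = n),
                   group = unname(lg[rep(lines, length.out = n)]),
                   zygosity = zyg)
  as_singleton_set(df, lg)
}

# Random cohort table; dup_frac of the loci share a position with another
# locus (different alt), exercising the positional uniqueness rule.
random_cohort <- function(n_loci, n_lines, dup_frac = 0.05,
                          p_cell = c(hom_ref = 0.85, het = 0.08,
                                     hom_alt = 0.04, missing = 0.03)) {
  n_dup <- floor(n_loci * dup_frac)
  base_pos <- sample.int(n_loci * 50, n_loci - n_dup)
  pos <- c(base_pos, sample(base_pos, n_dup))
  ref <- sample(c("A", "C", "G", "T"), n_loci, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  key <- paste(pos, ref, alt)
  keep <- !duplicated(key)
  loci <- data.frame(contig = "chr1", pos = pos, ref = ref,
                     alt = alt)[keep, ]
  gt <- matrix(sample(names(p_cell), nrow(loci) * n_lines, replace = TRUE,
                      prob = p_cell),
               nrow(loci), n_lines,
               dimnames = list(NULL, paste0("L", seq_len(n_lines))))
  lg <- setNames(rep(c("CK", "TX"), length.out = n_lines),
                 colnames(gt))
  cohort_table(loci, gt, lg)
}

# Brute-force filter + singleton oracle: per-locus recount with plain loops.
naive_filter_singletons <- function(table, max_missing = 0.2,
                                    max_het = 0.2) {
  gt <- table$genotypes
  keep <- logical(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    row <- gt[i, ]
    fm <- sum(row == "missing") / length(row)
    nm <- sum(row != "missing")
    fh <- if (nm == 0) 0 else sum(row == "het") / nm
    keep[i] <- !(fm > max_missing || fh > max_het)
  }
  loci <- table$loci[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(gt))) {
    carriers <- colnames(gt)[gt[i, ] %in% c("het", "hom_alt")]
    if (length(carriers) != 1) next
    same_pos <- which(loci$contig == loci$contig[i] & loci$pos == loci$pos[i])
    all_carriers <- unique(unlist(lapply(same_pos, function(j)
      colnames(gt)[gt[j, ] %in% c("het", "hom_alt")])))
    if (length(all_carriers) == 1)
      out[[length(out) + 1]] <- data.frame(
        contig = loci$contig[i], pos = loci$pos[i], ref = loci$ref[i],
        alt = loci$alt[i], line = carriers)
  }
  if (length(out) == 0)
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      line = character()))
  df <- do.call(rbind, out)
  df[order(df$contig, df$pos, df$line), ]
}

# Naive GFF feature scan over a plain feature table.
naive_feature_scan <- function(features, contig, pos) {
  hit <- features$contig == contig & features$start <= pos &
    features$end >= pos
  unique(features$type[hit])
}

# rle-based homopolymer adjacency oracle over a +/- window around the
# affected interval (independent mechanics from the implementation).
naive_hp_adjacent <- function(seq, pos, ref, alt, min_run = 4) {
  is_ins <- nchar(alt) > nchar(ref)
  istart <- pos + 1
  iend <- if (is_ins) pos else pos + nchar(ref) - 1
  sq <- if (is_ins) substring(alt, 2) else substring(ref, 2)
  run_at <- function(p, dir) {
    if (p < 1 || p > nchar(seq)) return(c(run = 0))
    lo <- max(1, p - 40); hi <- min(nchar(seq), p + 40)
    chars <- strsplit(substring(seq, lo, hi), "")[[1]]
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- which(starts <= (p - lo + 1) & ends >= (p - lo + 1))
    len <- if (dir == "left") (p - lo + 1) - starts[k] + 1
           else ends[k] - (p - lo + 1) + 1
    c(run = len, base = r$values[k])
  }
  l <- run_at(istart - 1, "left"); r <- run_at(iend + 1, "right")
  if (as.integer(l["run"]) >= min_run || as.integer(r["run"]) >= min_run)
    return(TRUE)
  ch <- unique(strsplit(sq, "")[[1]])
  if (length(ch) == 1) {
    m <- nchar(sq)
    el <- m + if (!is.na(l["base"]) && l["base"] == ch)
      as.integer(l["run"]) else 0
    er <- m + if (!is.na(r["base"]) && r["base"] == ch)
      as.integer(r["run"]) else 0
    if (el >= min_run || er >= min_run) return(TRUE)
  }
  FALSE
}

# Brute-force tandem-repeat adjacency oracle.
naive_rep_adjacent <- function(seq, pos, ref, alt, unit_sizes = 2:3,
                               min_copies = 3) {
  is_ins <- nchar(alt) > nchar(ref)
  istart <- pos + 1
  iend <- if (is_ins) pos else pos + nchar(ref) - 1
  sq <- if (is_ins) substring(alt, 2) else substring(ref, 2)
  count_copies <- function(boundary, unit, side) {
    u <- nchar(unit); n <- 0; p <- boundary
    repeat {
      piece <- if (side == "left") {
        if (p - u + 1 < 1) break
        substring(seq, p - u + 1, p)
      } else {
        if (p + u - 1 > nchar(seq)) break
        substring(seq, p, p + u - 1)
      }
      if (piece != unit) break
      n <- n + 1
      p <- if (side == "left") p - u else p + u
    }
    n
  }
  seq_copies_of <- function(s, unit) {
    u <- nchar(unit)
    if (nchar(s) == 0 || nchar(s) %% u != 0) return(0)
    if (paste(rep(unit, nchar(s) / u), collapse = "") == s) nchar(s) / u
    else 0
  }
  for (u in unit_sizes) {
    lb <- istart - 1; rb <- iend + 1
    if (lb - u + 1 >= 1) {
      unit <- substring(seq, lb - u + 1, lb)
      cl <- count_copies(lb, unit, "left")
      if (cl >= min_copies) return(TRUE)
      if (seq_copies_of(sq, unit) > 0 &&
          cl + seq_copies_of(sq, unit) >= min_copies) return(TRUE)
    }
    if (rb + u - 1 <= nchar(seq)) {
      unit <- substring(seq, rb, rb + u - 1)
      cr <- count_copies(rb, unit, "right")
      if (cr >= min_copies) return(TRUE)
      if (seq_copies_of(sq, unit) > 0 &&
          cr + seq_copies_of(sq, unit) >= min_copies) return(TRUE)
    }
  }
  FALSE
}

# Closed-form one-way ANOVA + Tukey-Kramer oracle (independent of aov /
# TukeyHSD).
anova_tukey_oracle <- function(values, groups) {
  sp <- split(values, groups)
  k <- length(sp); N <- length(values)
  ni <- vapply(sp, length, numeric(1))
  mi <- vapply(sp, mean, numeric(1))
  gm <- mean(values)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(sp, function(x) sum((x - mean(x))^2), numeric(1)))
  dfb <- k - 1; dfw <- N - k
  mse <- ssw / dfw
  f <- (ssb / dfb) / mse
  p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  pairs <- t(utils::combn(names(sp), 2))
  q <- abs(mi[pairs[, 1]] - mi[pairs[, 2]]) /
    sqrt(mse / 2 * (1 / ni[pairs[, 1]] + 1 / ni[pairs[, 2]]))
  padj <- stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
  list(f = f, p = p,
       tukey = data.frame(a = pairs[, 1], b = pairs[, 2],
                          p_adj = unname(padj)))
}

# Closed-form Welch two-sample two-sided t-test oracle.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Tiny uniform random genome as a reference_genome.
random_genome <- function(len, gc = 0.5, name = "chr1") {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  reference_genome(setNames(
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    name))
}

# Binomial 99% CI half-widths used by recovery checks.
binom_ci99 <- function(p, n) 2.576 * sqrt(p * (1 - p) / n)
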