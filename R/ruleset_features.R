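# Rule Set 2 featurization of a 30-mer scoring context: position-dependent
# single/dinucleotide one-hots, position-independent counts, GC features, the
# PAM-bookend dinucleotide, and four nearest-neighbor melting temperatures.
#
# 30-mer layout (1-based): 1-4 = 5' flank, 5-24 = protospacer, 25-27 = PAM
# slot, 28-30 = 3' flank.

DINUCS <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
DINUCS <- DINUCS[order(DINUCS)]

#' Canonical feature registry
#'
#' The fixed, ordered list of the 627 feature names produced by
#' [featurize()]. Models store this registry so that serialized models can be
#' checked against the featurizer that scores new sequences.
#'
#' @return character vector of 627 feature names.
#' @export
feature_registry <- function() {
  c(
    as.vector(t(outer(sprintf("pos%02d", 1:30), DNA_BASES,
                      function(p, b) paste0(p, "_", b)))),
    as.vector(t(outer(sprintf("dipos%02d", 1:29), DINUCS,
                      function(p, d) paste0(p, "_", d)))),
    paste0("count_", DNA_BASES),
    paste0("dicount_", DINUCS),
    "gc_count", "gc_above_10", "gc_below_10",
    paste0("bookend_", DINUCS),
    "tm_30mer", "tm_5mer_prox", "tm_8mer", "tm_5mer_distal"
  )
}

check_context30 <- function(ctx) {
  if (any(nchar(ctx) != 30L)) stop("scoring context must be exactly 30 bp")
  if (any(!is_acgt(ctx))) stop("scoring context must contain only A/C/G/T")
  invisible(ctx)
}

#' Rule Set 2 feature vector(s) for 30-mer contexts
#'
#' Converts one or more 30-mer contexts into the named 627-feature vector of
#' the Rule Set 2 scheme: one-hot single nucleotides at positions 1--30 (120),
#' one-hot dinucleotides at positions 1--29 (464), position-independent
#' single/dinucleotide counts over the 30-mer (4 + 16), GC count of the
#' protospacer (positions 5--24) with `gc_above_10`/`gc_below_10` flags (3),
#' the one-hot dinucleotide formed by the bases bookending the PAM "GG"
#' (positions 25 and 28; 16), and four melting temperatures (4).
#'
#' @param ctx character vector of 30-mers.
#' @return for a single context, a named numeric vector in registry order;
#'   for several, a numeric matrix with one row per context.
#' @export
featurize <- function(ctx) {
  check_context30(ctx)
  reg <- feature_registry()
  n <- length(ctx)
  M <- matrix(0, nrow = n, ncol = length(reg), dimnames = list(NULL, reg))
  ch <- matrix(unlist(strsplit(ctx, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  rows <- seq_len(n)
  for (k in 1:30) {
    M[cbind(rows, match(sprintf("pos%02d_%s", k, ch[, k]), reg))] <- 1
  }
  di <- matrix(paste0(ch[, 1:29, drop = FALSE], ch[, 2:30, drop = FALSE]),
               nrow = n)
  for (k in 1:29) {
    M[cbind(rows, match(sprintf("dipos%02d_%s", k, di[, k]), reg))] <- 1
  }
  for (b in DNA_BASES) M[, paste0("count_", b)] <- rowSums(ch == b)
  for (d in DINUCS) M[, paste0("dicount_", d)] <- rowSums(di == d)
  gc <- rowSums(ch[, 5:24, drop = FALSE] == "G" | ch[, 5:24, drop = FALSE] == "C")
  M[, "gc_count"] <- gc
  M[, "gc_above_10"] <- as.numeric(gc > 10)
  M[, "gc_below_10"] <- as.numeric(gc < 10)
  M[cbind(rows, match(paste0("bookend_", ch[, 25], ch[, 28]), reg))] <- 1
  tms <- tm_features(ctx)
  M[, colnames(tms)] <- tms
  if (n == 1L) M[1L, ] else M
}

# Allawi & SantaLucia (1997) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); complementary stacks share values.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # per G/C or A/T duplex terminus
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Nearest-neighbor DNA melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor model with the
#' Allawi & SantaLucia stacked-pair enthalpy/entropy increments and terminal
#' initiation corrections:
#' `Tm = 1000 * dH / (dS + R * ln(C/4)) - 273.15 + 16.6 * log10([Na+])`,
#' with `R = 1.987` cal/(K mol), strand concentration `C` (the `C/4` term
#' assumes a non-self-complementary duplex) and a monovalent-salt correction.
#'
#' @param seq DNA string, length >= 2, A/C/G/T only.
#' @param strand_conc strand concentration in mol/L (default 5e-8, i.e. 50 nM).
#' @param na_conc monovalent sodium concentration in mol/L (default 0.05).
#' @param terminal_correction apply the terminal A/T / G/C initiation terms
#'   (default TRUE).
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, strand_conc = 5e-8, na_conc = 0.05,
                                terminal_correction = TRUE) {
  seq <- toupper(seq)
  if (nchar(seq) < 2L) stop("melting temperature needs at least 2 bases")
  if (!is_acgt(seq)) stop("melting temperature requires A/C/G/T only")
  ch <- seq_chars(seq)
  stacks <- paste0(ch[-length(ch)], ch[-1L])
  dh <- sum(NN_DH[stacks])
  ds <- sum(NN_DS[stacks])
  if (terminal_correction) {
    for (term in ch[c(1L, length(ch))]) {
      cls <- if (term %in% c("G", "C")) "GC" else "AT"
      dh <- dh + NN_INIT_DH[[cls]]
      ds <- ds + NN_INIT_DS[[cls]]
    }
  }
  R <- 1.987
  tm <- 1000 * dh / (ds + R * log(strand_conc / 4)) - 273.15
  tm + 16.6 * log10(na_conc)
}

#' Thermodynamic features of a 30-mer context
#'
#' The four melting temperatures used by the efficiency model: the whole
#' 30-mer, the 5-mer immediately proximal to the PAM (positions 20--24), the
#' 8-mer upstream of it (positions 12--19), and the next 5-mer upstream
#' (positions 7--11).
#'
#' @param ctx character vector of 30-mer contexts.
#' @param ... passed to [melting_temperature()].
#' @return numeric matrix with columns `tm_30mer`, `tm_5mer_prox`, `tm_8mer`,
#'   `tm_5mer_distal`, one row per context.
#' @export
tm_features <- function(ctx, ...) {
  check_context30(ctx)
  f <- function(a, b) vapply(substring(ctx, a, b), melting_temperature, numeric(1), ...)
  cbind(tm_30mer = f(1, 30),
        tm_5mer_prox = f(20, 24),
        tm_8mer = f(12, 19),
        tm_5mer_distal = f(7, 11))
}
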