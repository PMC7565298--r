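# Nearest-neighbor RNA/RNA duplex free-energy parameters at 37 degrees C
# (Turner 2004 set; kcal/mol).  Values are shipped as versioned constants:
# stacking free energies for all Watson-Crick and G:U stacked pairs, bulge
# and internal-loop initiation penalties by loop size, the Ninio asymmetry
# term, the bimolecular duplex initiation penalty and the terminal-AU/GU
# penalty.  Only the parameters needed for intermolecular duplexes are
# included (no hairpin or multiloop terms: neither strand folds on itself).

.PAIR_TYPES <- c("CG", "GC", "GU", "UG", "AU", "UA")

# Stacking free energies, indexed [p1, rev(p2)] for the duplex
#   5'-A B-3'
#   3'-U V-5'
# with p1 = (A,U), p2 = (B,V) and rev(p2) = (V,B).
.STACK <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,   # CG
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,   # GC
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,   # GU
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,   # UG
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,   # AU
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30),  # UA
  nrow = 6, byrow = TRUE, dimnames = list(.PAIR_TYPES, .PAIR_TYPES))

# Loop initiation penalties by loop size (kcal/mol); index = number of
# unpaired nucleotides.  Bulge: one-sided loops; internal: total size over
# both sides (minimum 2).
.BULGE_INIT <- c(3.80, 2.80, 3.20, 3.60, 4.00, 4.40, 4.60, 4.70, 4.80,
                 4.90, 5.00, 5.10, 5.20, 5.30, 5.40, 5.40, 5.50, 5.50)
.INTERNAL_INIT <- c(NA, 1.00, 1.00, 1.10, 2.00, 2.00, 2.10, 2.30, 2.40,
                    2.50, 2.60, 2.70, 2.80, 2.90, 2.90, 3.00, 3.10, 3.10)

#' Nearest-neighbor duplex energy model
#'
#' Returns the shipped RNA/RNA nearest-neighbor free-energy parameter set
#' (37 degrees C) used by [duplex_mfe()] and [predict_targets()].  Stacking
#' energies cover all Watson-Crick and G:U stacked pairs; loop penalties are
#' initiation terms by loop size plus a capped asymmetry (Ninio) term for
#' internal loops; bimolecular initiation and terminal-AU/GU penalties close
#' the duplex.
#'
#' @return An object of class `energy_model`: a list with elements `stack`
#'   (6 x 6 matrix over pair types CG, GC, GU, UG, AU, UA), `bulge` and
#'   `internal` (loop initiation penalties by size), `ninio`
#'   (`c(slope, max)`), `init` (duplex initiation, kcal/mol), `terminal_au`
#'   (penalty per AU or GU duplex-end pair) and `name` (parameter-set tag).
#' @examples
#' m <- energy_model()
#' m$stack["GC", "GC"]  # 5'-GC-3' / 3'-CG-5'
#' @export
energy_model <- function() {
  structure(list(
    stack       = .STACK,
    bulge       = .BULGE_INIT,
    internal    = .INTERNAL_INIT,
    ninio       = c(slope = 0.60, max = 3.00),
    init        = 4.10,
    terminal_au = 0.50,
    name        = "turner2004"
  ), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Nearest-neighbor RNA/RNA duplex energy model (", x$name, ")\n", sep = "")
  cat("  duplex initiation: +", format(x$init), " kcal/mol\n", sep = "")
  cat("  terminal AU/GU penalty: +", format(x$terminal_au), " kcal/mol\n", sep = "")
  cat("  stacks: 6 x 6 Watson-Crick / G:U table; WC range [",
      min(x$stack), ", ", max(x$stack[1:2, 1:2]), "]\n", sep = "")
  invisible(x)
}

# --- sequence utilities ----------------------------------------------------

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U.  Errors on characters outside ACGUT.
#'
#' @param x character vector of nucleotide strings (DNA or RNA, any case).
#' @return character vector over A, C, G, U.
#' @export
as_rna <- function(x) {
  out <- chartr("tT", "uU", toupper(x))
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  out
}

#' Reverse complement of an RNA string
#'
#' Watson-Crick reverse complement over the RNA alphabet (A<->U, C<->G).
#'
#' @param x character vector of RNA strings.
#' @return character vector of reverse complements.
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", as_rna(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Pair type of (a, b) where a is the base on the 5'->3' strand and b the base
# it faces on the antiparallel strand; NA if not Watson-Crick or G:U.
pair_type <- function(a, b) {
  pt <- paste0(a, b)
  ifelse(pt %in% .PAIR_TYPES, pt, NA_character_)
}

# TRUE iff the pair is Watson-Crick (no wobble).
is_wc_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC")
}

# Reverse a pair type string: "AU" -> "UA".
rev_pair <- function(pt) {
  paste0(substr(pt, 2, 2), substr(pt, 1, 1))
}

# Free-energy increment between two consecutive pairs of an intermolecular
# duplex: target positions i1 < i2 (5'->3'), miRNA positions j1 > j2
# (read 3'->5' along the target).  a, b are the unpaired gap lengths on the
# target and miRNA side.  Returns +Inf when the step violates the loop
# constraints.  `tb`, `mb`: single-character vectors of the two sequences.
step_energy <- function(i1, j1, i2, j2, tb, mb, model,
                        max_bulge = 9L, max_internal = 9L) {
  a <- i2 - i1 - 1L
  b <- j1 - j2 - 1L
  if (a < 0L || b < 0L) return(Inf)
  p1 <- pair_type(tb[i1], mb[j1])
  p2 <- pair_type(tb[i2], mb[j2])
  if (is.na(p1) || is.na(p2)) return(Inf)
  if (a == 0L && b == 0L) {
    return(model$stack[p1, rev_pair(p2)])
  }
  if (a == 0L || b == 0L) {            # bulge
    size <- a + b
    if (size > max_bulge) return(Inf)
    e <- model$bulge[size]
    # single-nucleotide bulges keep the flanking stack (standard NN rule)
    if (size == 1L) e <- e + model$stack[p1, rev_pair(p2)]
    return(e)
  }
  if (a > max_internal || b > max_internal) return(Inf)
  model$internal[a + b] +
    min(model$ninio[["max"]], model$ninio[["slope"]] * abs(a - b))
}

#' Score a duplex structure under the shipped energy model
#'
#' Independent structure-scoring function: given an explicit list of
#' intermolecular base pairs, returns the total free energy (initiation +
#' stacks + loop penalties + terminal corrections).  Used to validate that
#' every structure reported by the dynamic program of [duplex_mfe()]
#' re-scores to its reported minimum free energy, and by brute-force
#' enumeration oracles.
#'
#' @param pairs data.frame (or matrix) with columns `i` (position on the
#'   target, 1-based, 5'->3') and `j` (position on the miRNA, 1-based from
#'   its 5' end).  Pairs must be antiparallel: sorted by increasing `i`,
#'   `j` strictly decreasing.
#' @param target,mirna sequences (RNA or DNA; normalized internally).
#' @param model an [energy_model()].
#' @param max_bulge,max_internal loop constraints in nt (per side for
#'   internal loops).
#' @return free energy in kcal/mol; `Inf` if the structure is invalid
#'   (non-pairable bases, crossing pairs, or a loop above the constraints).
#' @export
score_duplex_structure <- function(pairs, target, mirna, model = energy_model(),
                                   max_bulge = 9L, max_internal = 9L) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) return(Inf)
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  tb <- strsplit(as_rna(target), "", fixed = TRUE)[[1]]
  mb <- strsplit(as_rna(mirna),  "", fixed = TRUE)[[1]]
  if (any(pairs$i < 1L | pairs$i > length(tb)) ||
      any(pairs$j < 1L | pairs$j > length(mb))) return(Inf)
  if (is.unsorted(rev(pairs$j), strictly = TRUE) &&
      nrow(pairs) > 1L) return(Inf)   # j must strictly decrease with i
  pt <- pair_type(tb[pairs$i], mb[pairs$j])
  if (anyNA(pt)) return(Inf)
  e <- model$init
  if (nrow(pairs) > 1L) {
    for (r in seq_len(nrow(pairs) - 1L)) {
      e <- e + step_energy(pairs$i[r], pairs$j[r],
                           pairs$i[r + 1L], pairs$j[r + 1L],
                           tb, mb, model, max_bulge, max_internal)
      if (!is.finite(e)) return(Inf)
    }
  }
  # terminal AU/GU penalty at both duplex ends
  for (pe in pt[c(1L, length(pt))]) {
    if (pe %in% c("AU", "UA", "GU", "UG")) e <- e + model$terminal_au
  }
  e
}
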