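#' @keywords internal
RNA_STOPS <- c("UAA", "UAG", "UGA")

# all 61 sense codons (RNA alphabet), with amino acids from the standard code
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- chartr("T", "U", names(gc))
  aa <- unname(gc)
  keep <- aa != "*"
  data.frame(codon = codons[keep], amino_acid = aa[keep],
             stringsAsFactors = FALSE)
}

normalize_codons <- function(x) chartr("Tt", "UU", toupper(x))

# per-amino-acid number of tRNA species of the synthetic 41-species key
.species_per_aa <- c(A = 2, R = 3, N = 1, D = 1, C = 1, Q = 2, E = 2, G = 3,
                     H = 1, I = 2, L = 5, K = 2, M = 1, F = 1, P = 2, S = 4,
                     T = 3, W = 1, Y = 1, V = 3)

.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val")

# synthetic gene copy numbers per species label (realistic yeast-like spread)
.synthetic_copies <- c(
  Ala1 = 11, Ala2 = 5, Arg1 = 11, Arg2 = 6, Arg3 = 1, Asn1 = 10, Asp1 = 16,
  Cys1 = 4, Gln1 = 9, Gln2 = 1, Glu1 = 14, Glu2 = 2, Gly1 = 16, Gly2 = 3,
  Gly3 = 2, His1 = 7, Ile1 = 13, Ile2 = 2, Leu1 = 1, Leu2 = 10, Leu3 = 2,
  Leu4 = 7, Leu5 = 1, Lys1 = 7, Lys2 = 14, Met1 = 5, Phe1 = 10, Pro1 = 10,
  Pro2 = 2, Ser1 = 11, Ser2 = 4, Ser3 = 3, Ser4 = 1, Thr1 = 11, Thr2 = 4,
  Thr3 = 1, Trp1 = 6, Tyr1 = 8, Val1 = 14, Val2 = 2, Val3 = 2)

#' Synthetic 41-species tRNA table
#'
#' A synthetic stand-in for the yeast tRNA species table: 41 species labelled
#' alphabetically by tRNA name (Ala1, Ala2, Arg1, ...), each decoding a
#' contiguous block of the synonymous codons of its amino acid, with gene
#' copy numbers drawn to emulate the real copy-number distribution (range
#' 1-16, total 269). It is NOT the measured yeast table; it reproduces its
#' structure (species count, alphabetical labelling, abundance spread) so
#' that all analyses run without external data. Override with your own table
#' via [load_trna_table()].
#'
#' @return data.frame with columns `id`, `label`, `anticodon`, `amino_acid`,
#'   `gene_copy_number`.
#' @export
#' @examples
#' nrow(synthetic_trna_table())  # 41
synthetic_trna_table <- function() {
  labels <- character(0)
  aas <- character(0)
  for (aa in names(.species_per_aa)) {
    n <- .species_per_aa[[aa]]
    labels <- c(labels, paste0(.aa3[[aa]], seq_len(n)))
    aas <- c(aas, rep(aa, n))
  }
  ord <- order(labels)
  labels <- labels[ord]; aas <- aas[ord]
  map <- synthetic_codon_assignment(labels, aas)
  first_codon <- vapply(seq_along(labels), function(i) {
    map$codon[map$species_id == i][1]
  }, character(1))
  anticodon <- vapply(first_codon, function(cd) {
    comp <- chartr("ACGU", "UGCA", cd)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1))
  data.frame(id = seq_along(labels),
             label = labels,
             anticodon = unname(anticodon),
             amino_acid = aas,
             gene_copy_number = unname(.synthetic_copies[labels]),
             stringsAsFactors = FALSE)
}

# deterministic codon -> species assignment: the sorted synonymous codons of
# each amino acid are split into contiguous chunks, one per species, with the
# earlier species taking the larger chunks
synthetic_codon_assignment <- function(labels, aas) {
  sc <- sense_codons()
  out_codon <- character(0)
  out_id <- integer(0)
  for (aa in unique(aas)) {
    ids <- which(aas == aa)
    cods <- sort(sc$codon[sc$amino_acid == aa])
    n <- length(ids)
    sizes <- rep(length(cods) %/% n, n)
    extra <- length(cods) %% n
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    pos <- 1
    for (j in seq_len(n)) {
      take <- cods[pos:(pos + sizes[j] - 1)]
      out_codon <- c(out_codon, take)
      out_id <- c(out_id, rep(ids[j], length(take)))
      pos <- pos + sizes[j]
    }
  }
  data.frame(codon = out_codon, species_id = out_id, stringsAsFactors = FALSE)
}

#' Synthetic codon-to-tRNA-species map
#'
#' Companion to [synthetic_trna_table()]: maps each of the 61 sense codons to
#' exactly one of the 41 species (no wobble splitting; wobble base pairing is
#' deliberately outside the model). Stop codons are absent by construction.
#'
#' @param trna tRNA table, defaults to [synthetic_trna_table()].
#' @return data.frame with columns `codon` (RNA alphabet) and `species_id`.
#' @export
synthetic_codon_map <- function(trna = synthetic_trna_table()) {
  map <- synthetic_codon_assignment(trna$label, trna$amino_acid)
  validate_codon_map(map, trna)
  map
}

#' Validate a codon map
#'
#' Checks the map invariants: exactly the 61 sense codons are mapped, the 3
#' stop codons are absent, every referenced species id exists in the tRNA
#' table, and no codon is mapped twice.
#'
#' @param map data.frame with columns `codon`, `species_id`.
#' @param trna tRNA table the ids must refer to.
#' @return the map, invisibly, with codons normalized to the RNA alphabet.
#' @export
validate_codon_map <- function(map, trna) {
  stopifnot(all(c("codon", "species_id") %in% names(map)))
  map$codon <- normalize_codons(map$codon)
  if (anyDuplicated(map$codon))
    stop("codon map contains duplicate codons: ",
         paste(unique(map$codon[duplicated(map$codon)]), collapse = ", "))
  if (any(map$codon %in% RNA_STOPS))
    stop("codon map must not contain stop codons")
  expected <- sort(sense_codons()$codon)
  if (!identical(sort(map$codon), expected)) {
    missing <- setdiff(expected, map$codon)
    extra <- setdiff(map$codon, expected)
    stop("codon map must cover exactly the 61 sense codons",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  if (!all(map$species_id %in% trna$id))
    stop("codon map references species ids absent from the tRNA table")
  invisible(map)
}

#' Map codon strings to tRNA species ids
#'
#' @param codons character vector of codons (DNA or RNA alphabet, any case).
#' @param map codon map data.frame.
#' @return integer vector of species ids.
#' @export
map_codons <- function(codons, map) {
  codons <- normalize_codons(codons)
  idx <- match(codons, normalize_codons(map$codon))
  if (anyNA(idx)) {
    bad <- unique(codons[is.na(idx)])
    stop("unmapped codon(s): ", paste(bad, collapse = ", "))
  }
  as.integer(map$species_id[idx])
}
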