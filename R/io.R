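#' Read ORF sequences from a FASTA file and map codons to tRNA species
#'
#' Each record is split into codons (DNA and RNA alphabets are treated
#' identically), the terminal stop codon is trimmed if present, and every
#' remaining codon is mapped to its tRNA species id. Stop codons are not
#' lattice sites: the model's termination step replaces stop-codon decoding,
#' so the transcript length L counts only codons decoded by aa-tRNAs.
#'
#' @param path FASTA file of ORF sequences.
#' @param map codon map (see [synthetic_codon_map()] / [load_codon_map()]).
#' @param internal_stop what to do when a stop codon occurs before the last
#'   codon: `"error"` (default) or `"truncate"` at the first internal stop.
#' @return list of mRNA records, each a list with `name`, `codons` (character
#'   codons, RNA alphabet) and `species` (integer tRNA species ids), in file
#'   order.
#' @export
read_orf_fasta <- function(path, map, internal_stop = c("error", "truncate")) {
  internal_stop <- match.arg(internal_stop)
  seqs <- Biostrings::readBStringSet(path)
  out <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    name <- sub("\\s.*$", "", names(seqs)[k])
    s <- normalize_codons(as.character(seqs[[k]]))
    if (nchar(s) %% 3 != 0)
      stop("record ", name, ": length ", nchar(s), " not multiple of 3")
    n <- nchar(s) %/% 3
    codons <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
    if (n >= 1 && codons[n] %in% RNA_STOPS) codons <- codons[-n]
    hit <- which(codons %in% RNA_STOPS)
    if (length(hit)) {
      if (internal_stop == "error")
        stop("record ", name, ": internal stop codon ", codons[hit[1]],
             " at codon ", hit[1])
      codons <- codons[seq_len(hit[1] - 1)]
    }
    if (!length(codons)) stop("record ", name, ": no sense codons")
    species <- tryCatch(map_codons(codons, map), error = function(e)
      stop("record ", name, ": ", conditionMessage(e), call. = FALSE))
    out[[k]] <- list(name = name, codons = codons, species = species)
  }
  out
}

#' Write ORF records to FASTA
#'
#' Inverse of [read_orf_fasta()] for records that carry codon strings; a
#' terminal UAA stop is appended to each sequence.
#'
#' @param orfs list of records with `name` and `codons`.
#' @param path output file.
#' @export
write_orf_fasta <- function(orfs, path) {
  lines <- unlist(lapply(orfs, function(m) {
    hdr <- paste0(">", m$name,
                  if (!is.null(m$desc)) paste0(" ", m$desc) else "")
    c(hdr, paste0(paste(m$codons, collapse = ""), "UAA"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Load a tRNA species table from TSV
#'
#' Expected columns: `id`, `label`, `anticodon`, `amino_acid`,
#' `gene_copy_number` (tab separated, with header). Kinetic fields (`T`, `E`,
#' `V`, `K`) are populated later by [build_system()].
#'
#' @param path TSV file.
#' @return validated data.frame ordered by id.
#' @export
load_trna_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("id", "label", "amino_acid", "gene_copy_number")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("tRNA table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("tRNA table has duplicate species ids")
  tab <- tab[order(tab$id), , drop = FALSE]
  if (!identical(as.integer(tab$id), seq_len(nrow(tab))))
    stop("species ids must be 1..S without gaps")
  g <- tab$gene_copy_number
  if (any(is.na(g)) || any(g <= 0) || any(g != round(g)))
    stop("gene copy numbers must be positive integers")
  tab$gene_copy_number <- as.integer(g)
  rownames(tab) <- NULL
  tab
}

#' Load a codon map from TSV
#'
#' Expected columns: `codon`, `species_id`. The map is validated against the
#' tRNA table (61 sense codons mapped, stops absent, ids known).
#'
#' @param path TSV file.
#' @param trna tRNA table the species ids refer to.
#' @return validated data.frame.
#' @export
load_codon_map <- function(path, trna) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "species_id") %in% names(map)))
    stop("codon map needs columns codon, species_id")
  map$codon <- normalize_codons(map$codon)
  validate_codon_map(map, trna)
  map$species_id <- as.integer(map$species_id)
  map
}

#' Write tables to TSV (tRNA table / codon map helper)
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation results to a directory
#'
#' Writes one density-profile TSV per mRNA species (columns `position`,
#' `reader_density`, `coverage_density`), a `charging.tsv` with per-tRNA
#' charging levels, a `summary.tsv` of key-value scalars (currents, mean
#' densities, ribosomes per codon), and, when given, an `analytics.tsv` with
#' the per-species supply/demand/critical-rate table.
#'
#' @param obs observable set from [run_simulation()].
#' @param outdir output directory (created if needed).
#' @param ana optional analytics table from [critical_alphas()].
#' @return `outdir`, invisibly.
#' @export
write_results <- function(obs, outdir, ana = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  for (nm in names(obs$profiles)) {
    write_tsv_table(obs$profiles[[nm]],
                    file.path(outdir, paste0("profile_", nm, ".tsv")))
  }
  write_tsv_table(obs$charging, file.path(outdir, "charging.tsv"))
  sp <- obs$species
  kv <- data.frame(
    key = c(paste0("J_", sp$name), paste0("J_se_", sp$name),
            paste0("reader_density_", sp$name),
            paste0("coverage_density_", sp$name),
            "ribosomes_per_codon", "measure_time", "n_events"),
    value = c(sp$J, sp$J_se, sp$reader_density, sp$coverage_density,
              obs$ribosomes_per_codon, obs$measure, obs$n_events),
    stringsAsFactors = FALSE)
  write_tsv_table(kv, file.path(outdir, "summary.tsv"))
  if (!is.null(ana)) write_tsv_table(ana, file.path(outdir, "analytics.tsv"))
  invisible(outdir)
}

#' Read back results written by [write_results()]
#'
#' @param outdir directory written by [write_results()].
#' @return list with `profiles`, `charging`, `summary`.
#' @export
read_results <- function(outdir) {
  prof_files <- list.files(outdir, pattern = "^profile_.*\\.tsv$",
                           full.names = TRUE)
  profiles <- lapply(prof_files, read.delim)
  names(profiles) <- sub("^profile_(.*)\\.tsv$", "\\1", basename(prof_files))
  list(profiles = profiles,
       charging = read.delim(file.path(outdir, "charging.tsv")),
       summary = read.delim(file.path(outdir, "summary.tsv")))
}
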