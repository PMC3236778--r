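#' Define an oligonucleotide
#'
#' Creates the description of one oligonucleotide used to assemble a tethered
#' DNA substrate. Only lengths and annealing registers matter for the derived
#' geometry; the sequence is optional and, when supplied for both strands, is
#' checked for exact reverse complementarity.
#'
#' @param name Oligo name.
#' @param length Length in nucleotides. May be omitted when `sequence` is given.
#' @param sequence Optional nucleotide sequence (A/C/G/T).
#' @param label5,label3 Optional 5'/3' chemical labels (e.g. `"dig"`,
#'   `"biotin"`). Labels identify the surface anchor and the bead attachment.
#' @param anneal_start,anneal_end Optional 1-based inclusive positions on the
#'   scaffold strand this oligo pairs with. The paired stretch may be shorter
#'   than the oligo, in which case the remainder is a single-stranded tail.
#'
#' @return An object of class `oligo_spec`.
#' @examples
#' oligo("C", length = 90, label3 = "biotin", anneal_start = 38, anneal_end = 127)
#' @export
oligo <- function(name, length = NULL, sequence = NULL, label5 = NULL,
                  label3 = NULL, anneal_start = NULL, anneal_end = NULL) {
  if (!is.null(sequence)) {
    sequence <- toupper(gsub("\\s", "", sequence))
    if (grepl("[^ACGT]", sequence))
      stop("oligo '", name, "': sequence contains non-ACGT characters")
    if (is.null(length)) length <- nchar(sequence)
    if (nchar(sequence) != length)
      stop("oligo '", name, "': sequence length (", nchar(sequence),
           ") does not match length field (", length, ")")
  }
  if (is.null(length) || length < 1)
    stop("oligo '", name, "': length must be >= 1")
  length <- as.integer(length)
  if (xor(is.null(anneal_start), is.null(anneal_end)))
    stop("oligo '", name, "': give both anneal_start and anneal_end or neither")
  if (!is.null(anneal_start)) {
    anneal_start <- as.integer(anneal_start)
    anneal_end <- as.integer(anneal_end)
    if (anneal_end < anneal_start)
      stop("oligo '", name, "': anneal_end < anneal_start")
    if (anneal_end - anneal_start + 1L > length)
      stop("oligo '", name, "': anneal interval longer than the oligo")
  }
  structure(list(name = name, length = length, sequence = sequence,
                 label5 = label5, label3 = label3,
                 anneal_start = anneal_start, anneal_end = anneal_end),
            class = "oligo_spec")
}

#' @export
print.oligo_spec <- function(x, ...) {
  cat("<oligo_spec> ", x$name, ": ", x$length, " nt", sep = "")
  if (!is.null(x$anneal_start))
    cat(", anneals ", x$anneal_start, "-", x$anneal_end, sep = "")
  if (!is.null(x$label5)) cat(", 5'-", x$label5, sep = "")
  if (!is.null(x$label3)) cat(", 3'-", x$label3, sep = "")
  cat("\n")
  invisible(x)
}

#' Anneal partner oligos onto a scaffold strand
#'
#' Assembles a tethered DNA substrate from a scaffold oligo and a set of
#' partner oligos, each pairing a stated 1-based inclusive interval of the
#' scaffold, and derives its geometry: total duplex length, 5' single-stranded
#' overhang of the scaffold, number of nicks (adjacent partner junctions) and
#' the length of unwindable duplex carried by the bead-labelled strand.
#'
#' @param scaffold An [oligo()] serving as the continuous strand.
#' @param partners List of [oligo()]s with annealing coordinates on the
#'   scaffold. Intervals must lie inside the scaffold and must not overlap.
#' @param unwindable_bp Length (bp) of the duplex whose unwinding releases the
#'   bead. Defaults to the paired length of the partner carrying a biotin
#'   label (the bead strand), or `NA` if there is none.
#' @param check_sequences Verify reverse complementarity where sequences are
#'   available (default `TRUE`; only fully paired partners are checked).
#'
#' @return An object of class `substrate_spec` with fields `scaffold`,
#'   `partners`, `duplex_bp`, `overhang5_nt`, `nicks`, `unwindable_bp`,
#'   `ss_nt` (total single-stranded nucleotides in the tether path before any
#'   unwinding).
#' @seealso [composition_at()], [fork_ac90()], [mimic_unwound()]
#' @export
anneal <- function(scaffold, partners, unwindable_bp = NULL,
                   check_sequences = TRUE) {
  stopifnot(inherits(scaffold, "oligo_spec"))
  if (length(partners) == 0L) {
    return(structure(list(scaffold = scaffold, partners = list(),
                          duplex_bp = 0L, overhang5_nt = scaffold$length,
                          nicks = 0L, unwindable_bp = NA_integer_,
                          ss_nt = scaffold$length),
                     class = "substrate_spec"))
  }
  for (p in partners) {
    if (!inherits(p, "oligo_spec")) stop("partners must be oligo_spec objects")
    if (is.null(p$anneal_start))
      stop("partner '", p$name, "' has no annealing coordinates")
    if (p$anneal_start < 1L || p$anneal_end > scaffold$length)
      stop("partner '", p$name, "' anneals outside the scaffold (1-",
           scaffold$length, ")")
  }
  ord <- order(vapply(partners, `[[`, integer(1), "anneal_start"))
  partners <- partners[ord]
  starts <- vapply(partners, `[[`, integer(1), "anneal_start")
  ends <- vapply(partners, `[[`, integer(1), "anneal_end")
  if (length(partners) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("partner annealing intervals overlap on the scaffold")

  paired <- ends - starts + 1L
  duplex_bp <- sum(paired)
  overhang5_nt <- starts[1L] - 1L
  nicks <- if (length(partners) > 1L)
    sum(starts[-1L] == ends[-length(ends)] + 1L) else 0L
  tails <- vapply(partners, `[[`, integer(1), "length") - paired
  ss_nt <- (scaffold$length - duplex_bp) + sum(tails)

  if (check_sequences && !is.null(scaffold$sequence)) {
    for (i in seq_along(partners)) {
      p <- partners[[i]]
      if (is.null(p$sequence) || paired[i] != p$length) next
      seg <- substr(scaffold$sequence, starts[i], ends[i])
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
      if (!identical(rc, p$sequence))
        stop("partner '", p$name, "' is not the reverse complement of ",
             "scaffold positions ", starts[i], "-", ends[i])
    }
  }

  if (is.null(unwindable_bp)) {
    is_bead <- vapply(partners, function(p) {
      any(vapply(c(p$label5, p$label3), identical, logical(1), "biotin"))
    }, logical(1))
    unwindable_bp <- if (any(is_bead)) sum(paired[is_bead]) else NA_integer_
  }

  structure(list(scaffold = scaffold, partners = partners,
                 duplex_bp = as.integer(duplex_bp),
                 overhang5_nt = as.integer(overhang5_nt),
                 nicks = as.integer(nicks),
                 unwindable_bp = as.integer(unwindable_bp),
                 ss_nt = as.integer(ss_nt)),
            class = "substrate_spec")
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat("<substrate_spec> scaffold ", x$scaffold$name, " (", x$scaffold$length,
      " nt) + ", length(x$partners), " partner(s)\n", sep = "")
  cat("  duplex: ", x$duplex_bp, " bp | 5' overhang: ", x$overhang5_nt,
      " nt | nicks: ", x$nicks, " | single-stranded: ", x$ss_nt,
      " nt | unwindable: ", x$unwindable_bp, " bp\n", sep = "")
  invisible(x)
}

#' Tether composition after partial unwinding
#'
#' Per base pair unwound, one duplex base pair is lost and both strands of the
#' opened pair become single-stranded along the surface-to-bead path, so the
#' single-stranded count grows by two nucleotides. The bead is released exactly
#' when the whole unwindable duplex is open.
#'
#' @param substrate A [anneal()] result.
#' @param unwound Base pairs unwound, `0 <= unwound <= unwindable_bp`.
#' @return An object of class `tether_composition`: `duplex_bp`, `ss_nt`,
#'   `bead_attached`.
#' @examples
#' composition_at(fork_ac90(), 45)
#' @export
composition_at <- function(substrate, unwound) {
  stopifnot(inherits(substrate, "substrate_spec"))
  if (is.na(substrate$unwindable_bp))
    stop("substrate has no unwindable (bead-strand) duplex")
  unwound <- as.integer(unwound)
  if (unwound < 0L || unwound > substrate$unwindable_bp)
    stop("unwound must be in [0, ", substrate$unwindable_bp, "]")
  structure(list(duplex_bp = substrate$duplex_bp - unwound,
                 ss_nt = substrate$ss_nt + 2L * unwound,
                 bead_attached = unwound < substrate$unwindable_bp),
            class = "tether_composition")
}

#' @export
print.tether_composition <- function(x, ...) {
  cat("<tether_composition> duplex ", x$duplex_bp, " bp, ssDNA ", x$ss_nt,
      " nt, bead ", if (x$bead_attached) "attached" else "released", "\n",
      sep = "")
  invisible(x)
}

#' The fork substrate used for unwinding experiments
#'
#' Three annealed oligos: a 145-nt scaffold (A), an 18-nt digoxigenin-labelled
#' surface anchor (B) pairing the scaffold 3' end, and a 90-nt biotinylated
#' bead strand (C) pairing the adjacent interval. The assembly has a 108 bp
#' duplex, a 37-nt 5' single-stranded overhang for helicase loading, one nick,
#' and a 90 bp unwindable duplex whose opening releases the bead.
#'
#' @return A `substrate_spec`.
#' @export
fork_ac90 <- function() {
  anneal(
    oligo("A", 145),
    list(oligo("B", 18, label5 = "dig", anneal_start = 128, anneal_end = 145),
         oligo("C", 90, label3 = "biotin", anneal_start = 38, anneal_end = 127))
  )
}

#' The mimicked-unwound control substrate
#'
#' The 145-nt scaffold is replaced by its 3'-terminal 37 nt, so oligo B
#' (18 nt) and only 19 nt of the 90-nt bead strand remain paired: a 37 bp
#' duplex with one nick and a 71-nt single-stranded tail on the bead strand,
#' mimicking the tether just before bead release.
#'
#' @return A `substrate_spec`.
#' @export
mimic_unwound <- function() {
  anneal(
    oligo("A37", 37),
    list(oligo("B", 18, label5 = "dig", anneal_start = 20, anneal_end = 37),
         oligo("C", 90, label3 = "biotin", anneal_start = 1, anneal_end = 19))
  )
}

#' Read oligo definitions from FASTA
#'
#' Annotations are carried as `key=value` tokens on the description line, e.g.
#' `>oligoB label5=dig anneal=128-145`. Recognised keys: `label5`, `label3`,
#' `anneal` (as `start-end`, 1-based inclusive on the scaffold).
#'
#' @param path FASTA file path.
#' @return A named list of `oligo_spec` objects.
#' @export
read_oligo_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    desc <- names(set)[i]
    toks <- strsplit(trimws(desc), "\\s+")[[1]]
    name <- toks[1L]
    kv <- toks[-1L][grepl("=", toks[-1L], fixed = TRUE)]
    fields <- list()
    for (t in kv) {
      parts <- strsplit(t, "=", fixed = TRUE)[[1]]
      fields[[parts[1L]]] <- parts[2L]
    }
    a <- NULL
    if (!is.null(fields$anneal)) {
      a <- as.integer(strsplit(fields$anneal, "-", fixed = TRUE)[[1]])
      if (length(a) != 2L || anyNA(a))
        stop("malformed anneal=start-end token for '", name, "'")
    }
    oligo(name, sequence = as.character(set[[i]]),
          label5 = fields$label5, label3 = fields$label3,
          anneal_start = a[1L], anneal_end = a[2L])
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write a substrate geometry report
#'
#' One row per substrate: name, duplex_bp, overhang5_nt, nicks, unwindable_bp.
#'
#' @param substrates Named list of `substrate_spec` objects.
#' @param path Output TSV path.
#' @return The report data frame, invisibly.
#' @export
write_substrate_report <- function(substrates, path) {
  if (is.null(names(substrates)))
    names(substrates) <- vapply(substrates, function(s) s$scaffold$name,
                                character(1))
  df <- data.frame(
    name = names(substrates),
    duplex_bp = vapply(substrates, `[[`, integer(1), "duplex_bp"),
    overhang5_nt = vapply(substrates, `[[`, integer(1), "overhang5_nt"),
    nicks = vapply(substrates, `[[`, integer(1), "nicks"),
    unwindable_bp = vapply(substrates, `[[`, integer(1), "unwindable_bp"),
    row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
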