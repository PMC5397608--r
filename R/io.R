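#' Read amino-acid sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; sequences are
#' upper-cased and letters outside the 20 canonical amino acids (plus `X`)
#' are kept but flagged via the `nonstandard` attribute.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case sequences, in file order.
#'   Records whose sequence contains letters outside the canonical alphabet
#'   carry their identifiers in `attr(, "nonstandard")`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot read FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA identifiers: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  odd <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% c(AA1, "X"))
  }, logical(1))
  if (any(odd)) attr(seqs, "nonstandard") <- ids[odd]
  seqs
}

#' Read protein chains from a PDB file
#'
#' ATOM records are parsed with [bio3d::read.pdb()]; waters and all HETATM
#' records are discarded, hydrogens are dropped, and alternate locations are
#' resolved to the highest-occupancy conformer (ties: first encountered).
#' Insertion codes are retained in the per-residue numbering.
#'
#' @param path Path to a PDB file.
#' @return An object of class `pdb_structure`: a list with `chains` (a named
#'   list, one entry per chain, each holding `chain_id`, `sequence`,
#'   `numbering` -- a data frame of `resno`/`ins` -- and `atoms`) and `atoms`,
#'   the full heavy-atom table used as occlusion context.
#' @export
read_pdb_chains <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot read PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(toupper(at$resid) %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy))
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  if (nrow(at) == 0L) stop("PDB file '", path, "' has no standard heavy atoms")
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at$occ <- ifelse(is.na(at$o), 1, at$o)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)

  # resolve altlocs per (chain, resno, ins, atom name): keep max occupancy,
  # ties broken by file order
  key <- paste(at$chain, at$resno, at$ins, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -at$occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$ins, at$elety,
                             sep = "\r")), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$ins, sep = "\r"),
                       unique(paste(at$chain, at$resno, at$ins, sep = "\r")))),
           , drop = FALSE]

  atoms <- data.frame(chain = at$chain, resno = at$resno, ins = at$ins,
                      resid = at$resid, elety = at$elety,
                      element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                                               substr(gsub("[0-9]", "",
                                                           at$elety), 1, 1),
                                               at$elesy)),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)

  chains <- list()
  for (ch in unique(atoms$chain)) {
    ca <- atoms[atoms$chain == ch, , drop = FALSE]
    rkey <- paste(ca$resno, ca$ins, sep = "\r")
    first <- !duplicated(rkey)
    resid <- ca$resid[first]
    seq1 <- suppressWarnings(three_to_one(resid))
    if (length(seq1) == 0L) {
      warning("chain ", ch, " has no standard residues; omitted")
      next
    }
    chains[[ch]] <- list(chain_id = ch,
                         sequence = paste(seq1, collapse = ""),
                         numbering = data.frame(resno = ca$resno[first],
                                                ins = ca$ins[first],
                                                aa = seq1,
                                                stringsAsFactors = FALSE),
                         atoms = ca)
  }
  if (length(chains) == 0L) stop("no usable chains in '", path, "'")
  structure(list(chains = chains, atoms = atoms), class = "pdb_structure")
}

#' Read a per-residue free-energy table
#'
#' Two dialects are supported. `generic_tsv` is the canonical interchange
#' format: a header `chain  position  aa  delta_g` followed by one row per
#' residue (position may carry a trailing insertion letter, e.g. `100A`).
#' `sequence_detail` accepts whitespace-separated rows in the layout produced
#' by FoldX's SequenceDetail command: three-letter amino acid, chain, residue
#' number, then energy columns; the column holding the total per-residue
#' energy is configurable because that layout varies between versions.
#'
#' @param path Path to the table.
#' @param dialect `"generic_tsv"` (default) or `"sequence_detail"`.
#' @param energy_column For `sequence_detail`: 1-based index, among the
#'   columns following the residue number, of the per-residue total energy.
#'   Default 1 (the first energy column).
#' @return A data frame of class `residue_energy_table` with columns
#'   `chain`, `position` (integer), `ins`, `aa`, `delta_g` (kcal/mol).
#' @export
read_residue_energy_table <- function(path,
                                      dialect = c("generic_tsv",
                                                  "sequence_detail"),
                                      energy_column = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("energy table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "generic_tsv") {
    if (length(lines) == 0L) stop("empty energy table: ", path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (!identical(tolower(trimws(header)),
                   c("chain", "position", "aa", "delta_g")))
      stop("generic_tsv header must be 'chain\tposition\taa\tdelta_g'")
    body <- lines[-1]
    body <- body[nzchar(trimws(body))]
    rows <- lapply(seq_along(body), function(i) {
      f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 4L)
        stop("malformed energy-table row at line ", i + 1L, ": ", body[i])
      pos <- parse_position(trimws(f[2]))
      dg <- suppressWarnings(as.numeric(trimws(f[4])))
      if (is.na(pos$number) || is.na(dg))
        stop("malformed energy-table row at line ", i + 1L, ": ", body[i])
      data.frame(chain = trimws(f[1]), position = pos$number, ins = pos$ins,
                 aa = toupper(trimws(f[3])), delta_g = dg,
                 stringsAsFactors = FALSE)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chain = character(), position = integer(), ins = character(),
                 aa = character(), delta_g = numeric(),
                 stringsAsFactors = FALSE)
  } else {
    body <- lines[nzchar(trimws(lines))]
    body <- body[!grepl("^\\s*(#|SequenceDetail|output)", body,
                        ignore.case = TRUE)]
    rows <- lapply(seq_along(body), function(i) {
      f <- strsplit(trimws(body[i]), "\\s+")[[1]]
      if (length(f) < 3L + energy_column)
        stop("malformed SequenceDetail row at line ", i, ": ", body[i])
      aa3 <- toupper(f[1])
      if (!aa3 %in% names(AA3))
        stop("malformed SequenceDetail row at line ", i,
             " (unknown residue '", f[1], "')")
      pos <- parse_position(f[3])
      dg <- suppressWarnings(as.numeric(f[3L + energy_column]))
      if (is.na(pos$number) || is.na(dg))
        stop("malformed SequenceDetail row at line ", i, ": ", body[i])
      data.frame(chain = f[2], position = pos$number, ins = pos$ins,
                 aa = unname(AA3[aa3]), delta_g = dg, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
  }
  if (nrow(tab)) {
    key <- paste(tab$chain, tab$position, tab$ins, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- tab[duplicated(key), , drop = FALSE]
      stop("duplicate residue key(s) in energy table: ",
           paste(paste0(dup$chain, dup$position, dup$ins), collapse = ", "))
    }
    bad <- !tab$aa %in% c(AA1, "X")
    if (any(bad)) stop("invalid amino-acid code(s): ",
                       paste(unique(tab$aa[bad]), collapse = ", "))
  }
  class(tab) <- c("residue_energy_table", class(tab))
  tab
}

#' Write a per-residue free-energy table (generic TSV dialect)
#'
#' @param table A `residue_energy_table` (or data frame with the same
#'   columns).
#' @param path Output path.
#' @export
write_residue_energy_table <- function(table, path) {
  lines <- c("chain\tposition\taa\tdelta_g",
             if (nrow(table))
               paste(table$chain, paste0(table$position, table$ins),
                     table$aa, format_num(table$delta_g), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# "100" / "100A" -> list(number, ins)
parse_position <- function(text) {
  m <- regmatches(text, regexec("^([0-9]+)([A-Za-z]?)$", text))[[1]]
  if (length(m) == 0L) return(list(number = NA_integer_, ins = ""))
  list(number = as.integer(m[2]), ins = toupper(m[3]))
}

#' Parse a mutation string
#'
#' Mutations follow the compact antibody convention `<wt><chain><pos><mut>`,
#' e.g. `"SL50K"`: serine at light-chain position 50 mutated to lysine. An
#' optional insertion letter may follow the digits (`"FH100AP"` is position
#' 100, insertion A).
#'
#' @param text Mutation string.
#' @return A list of class `mutation_spec`: `wild_type`, `chain`, `position`,
#'   `ins`, `mutant`.
#' @export
parse_mutation_string <- function(text) {
  m <- regmatches(text,
                  regexec("^([A-Z])([A-Z])([0-9]+)([A-Z]?)([A-Z])$",
                          toupper(trimws(text))))[[1]]
  if (length(m) == 0L)
    stop("cannot parse mutation string '", text,
         "' (expected e.g. 'SL50K')")
  wt <- m[2]; chain <- m[3]; pos <- as.integer(m[4]); ins <- m[5]; mut <- m[6]
  if (!chain %in% c("H", "L"))
    stop("mutation chain must be 'H' or 'L', got '", chain, "' in ", text)
  if (!wt %in% AA1 || !mut %in% AA1)
    stop("unknown amino acid in mutation '", text, "'")
  if (wt == mut)
    stop("identity substitution in mutation '", text, "'")
  structure(list(wild_type = wt, chain = chain, position = pos,
                 ins = ins, mutant = mut),
            class = "mutation_spec")
}

#' @export
format.mutation_spec <- function(x, ...)
  paste0(x$wild_type, x$chain, x$position, x$ins, x$mutant)

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation>", format(x), "\n")
  invisible(x)
}

# fixed significant digits so that reports are byte-stable
format_num <- function(x, digits = 6L) {
  out <- formatC(signif(x, digits), format = "fg", digits = digits)
  trimws(out)
}

#' Write a pipeline result to CSV or JSON
#'
#' Column/key order is fixed by the object and floating-point values are
#' rendered with six significant digits, so equal inputs produce
#' byte-identical files.
#'
#' @param report A data frame (CSV or JSON) or a list (JSON only).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(report))
      stop("CSV reports require a data frame")
    df <- report
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- format_num(df[[j]])
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = ","), con)
    if (nrow(df))
      writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)
  } else {
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 6,
                             pretty = TRUE, dataframe = "rows")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con)
  }
  invisible(path)
}
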