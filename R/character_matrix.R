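# Discrete morphological character matrices.
#
# A `character_matrix` holds, per (taxon, character) cell, a set of allowed
# integer states: a single state, a polymorphic set ("any-of" semantics),
# or missing ('?'). The inapplicable symbol '-' is scored as missing (the
# standard non-hierarchical treatment). Per-character flags mark ordered
# (additive) characters, active/excluded characters, and weights.
# User-facing character indices are always 1-based; the on-disk TNT ccode
# convention is 0-based and is translated at parse time.

state_symbols <- c(0:9, LETTERS)

symbol_to_state <- function(ch) {
  s <- match(toupper(ch), as.character(state_symbols)) - 1L
  if (anyNA(s)) abort(paste0("unknown state symbol: ", ch[is.na(s)][1]))
  s
}

# tokenize one row of a matrix into per-cell state strings
# "[01]" / "(01)" / "{01}" -> "01"; "?" and "-" -> NA (missing)
tokenize_row <- function(txt, taxon) {
  chars <- strsplit(txt, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("[", "(", "{")) {
      close <- c("[" = "]", "(" = ")", "{" = "}")[[ch]]
      j <- i + 1L
      grp <- character(0)
      while (j <= length(chars) && chars[j] != close) {
        if (!chars[j] %in% c(" ", ",")) grp <- c(grp, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) {
        abort(paste0("taxon ", taxon, ": unclosed state group"))
      }
      out <- c(out, paste(grp, collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Construct a character matrix
#'
#' @param cells Character matrix (ntax x nchar) of cell tokens: a state
#'   symbol (`0`-`9`, `A`-`Z`), a string of several symbols for a
#'   polymorphic cell, or `?`/`-` for missing/inapplicable.
#' @param taxa Taxon names (unique, one per row).
#' @param ordered Logical per character (additive optimization), default
#'   all unordered.
#' @param active Logical per character; excluded characters never
#'   contribute to any score.
#' @param weights Numeric per character, default 1.
#' @return An object of class `character_matrix`.
#' @export
character_matrix <- function(cells, taxa,
                             ordered = NULL, active = NULL, weights = NULL) {
  cells <- as.matrix(cells)
  ntax <- nrow(cells)
  nchar_ <- ncol(cells)
  if (length(taxa) != ntax) abort("taxa length must match matrix rows")
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon: ", taxa[duplicated(taxa)][1]))
  }
  ordered <- ordered %||% rep(FALSE, nchar_)
  active <- active %||% rep(TRUE, nchar_)
  weights <- weights %||% rep(1, nchar_)
  stopifnot(length(ordered) == nchar_, length(active) == nchar_,
            length(weights) == nchar_)
  mask <- matrix(0L, ntax, nchar_)
  lo <- matrix(NA_integer_, ntax, nchar_)
  hi <- matrix(NA_integer_, ntax, nchar_)
  for (i in seq_len(ntax)) {
    for (j in seq_len(nchar_)) {
      tok <- cells[i, j]
      if (is.na(tok) || tok %in% c("?", "-")) next
      st <- symbol_to_state(strsplit(tok, "")[[1]])
      mask[i, j] <- sum(bitwShiftL(1L, unique(st)))
      lo[i, j] <- min(st)
      hi[i, j] <- max(st)
    }
  }
  out <- list(taxa = as.character(taxa), ntax = ntax, nchar = nchar_,
              cells = cells, mask = mask, lo = lo, hi = hi,
              ordered = as.logical(ordered), active = as.logical(active),
              weights = as.numeric(weights))
  class(out) <- "character_matrix"
  out
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix:", x$ntax, "taxa x", x$nchar, "characters\n")
  cat("  ordered:", sum(x$ordered), "  excluded:", sum(!x$active),
      "  missing cells:",
      sprintf("%.1f%%", 100 * mean(x$mask == 0L)), "\n")
  invisible(x)
}

#' @describeIn character_matrix Long tibble of cells (`taxon`,
#'   `character`, `states`).
#' @param x A `character_matrix`.
#' @param ... Unused.
#' @export
tidy.character_matrix <- function(x, ...) {
  tibble(taxon = rep(x$taxa, times = x$nchar),
         character = rep(seq_len(x$nchar), each = x$ntax),
         states = as.vector(x$cells))
}

apply_overrides <- function(cm, ordered = NULL, exclude = NULL) {
  if (!is.null(ordered)) {
    if (any(ordered < 1 | ordered > cm$nchar)) abort("ordered index out of range")
    cm$ordered[ordered] <- TRUE
  }
  if (!is.null(exclude)) {
    if (any(exclude < 1 | exclude > cm$nchar)) abort("excluded index out of range")
    cm$active[exclude] <- FALSE
  }
  cm
}

#' Read a morphological character matrix
#'
#' Parses TNT `xread` files (including `ccode` additivity/activity/weight
#' settings, translated from TNT's 0-based on-disk indices) and NEXUS
#' CHARACTERS/DATA blocks (including `TYPESET ord:` and `EXSET` lines in an
#' ASSUMPTIONS block, 1-based). Polymorphic cells may be bracketed with
#' `[]`, `()`, or `{}`; `?` is missing and `-` inapplicable (scored as
#' missing).
#'
#' @param path Path to the matrix file.
#' @param format `"auto"` (default, by content), `"tnt"`, or `"nexus"`.
#' @param ordered,exclude Optional 1-based character indices overriding or
#'   supplementing the file's own settings.
#' @param tnt_zero_based Treat indices inside TNT `ccode` blocks as 0-based
#'   (the TNT convention; default TRUE).
#' @return A `character_matrix`.
#' @export
read_character_matrix <- function(path, format = c("auto", "tnt", "nexus"),
                                  ordered = NULL, exclude = NULL,
                                  tnt_zero_based = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  txt <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^#NEXUS", txt, ignore.case = TRUE))) "nexus" else "tnt"
  }
  cm <- if (format == "tnt") {
    parse_tnt(txt, tnt_zero_based)
  } else {
    parse_nexus_matrix(txt)
  }
  apply_overrides(cm, ordered, exclude)
}

parse_tnt <- function(lines, tnt_zero_based) {
  txt <- paste(lines, collapse = "\n")
  m <- regexpr("xread", txt, ignore.case = TRUE)
  if (m < 0) abort("not a TNT xread file")
  rest <- substr(txt, m + 5L, nchar(txt))
  # optional quoted title
  rest <- sub("^\\s*'[^']*'", "", rest)
  hdr <- regmatches(rest, regexpr("^\\s*[0-9]+\\s+[0-9]+", rest))
  if (length(hdr) == 0) abort("xread header must give nchar and ntax")
  nums <- as.integer(strsplit(trimws(hdr), "\\s+")[[1]])
  nchar_ <- nums[1]; ntax <- nums[2]
  rest <- sub("^\\s*[0-9]+\\s+[0-9]+", "", rest)
  semi <- regexpr(";", rest, fixed = TRUE)
  if (semi < 0) abort("xread block not terminated by ';'")
  block <- substr(rest, 1, semi - 1L)
  commands <- substr(rest, semi + 1L, nchar(rest))
  rows <- strsplit(block, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[rows != "" & !grepl("^&", rows)]   # ignore interleave markers
  taxa <- character(0)
  data <- list()
  for (rw in rows) {
    parts <- regmatches(rw, regexpr("^\\S+", rw))
    taxon <- gsub("'", "", parts)
    seqtxt <- trimws(substr(rw, nchar(parts) + 1L, nchar(rw)))
    toks <- tokenize_row(seqtxt, taxon)
    if (taxon %in% taxa) {
      data[[taxon]] <- c(data[[taxon]], toks)   # interleaved continuation
    } else {
      taxa <- c(taxa, taxon)
      data[[taxon]] <- toks
    }
  }
  if (length(taxa) != ntax) {
    abort(paste0("xread declares ", ntax, " taxa but ", length(taxa), " found"))
  }
  badlen <- taxa[vapply(data, length, 1L) != nchar_]
  if (length(badlen) > 0) {
    abort(paste0("row length != ", nchar_, " for taxon: ",
                 paste(badlen, collapse = ", ")))
  }
  cells <- do.call(rbind, data[taxa])
  cells[cells %in% c("?", "-")] <- NA_character_
  cm <- character_matrix(cells, taxa)
  cm <- apply_ccode(cm, commands, tnt_zero_based)
  cm
}

# apply TNT ccode commands: ccode + 0 1 2 - 5 ] 10 [ 11 /2 3 ;
apply_ccode <- function(cm, commands, tnt_zero_based) {
  cc <- regmatches(commands,
                   gregexpr("ccode[^;]*;", commands, ignore.case = TRUE))[[1]]
  offset <- if (tnt_zero_based) 1L else 0L
  for (cmd in cc) {
    body <- sub(";$", "", sub("^\\s*ccode", "", cmd, ignore.case = TRUE))
    toks <- regmatches(body,
                       gregexpr("[][+*/-]|[0-9]+\\.[0-9]+|[0-9]+", body))[[1]]
    mode <- "+"
    weight <- 1
    expect_weight <- FALSE
    for (tk in toks) {
      if (tk %in% c("+", "-", "[", "]", "*", "/")) {
        mode <- tk
        expect_weight <- tk == "/"
        next
      }
      if (expect_weight) {
        weight <- as.numeric(tk)
        expect_weight <- FALSE
        next
      }
      if (grepl("\\.", tk)) {
        rng <- as.integer(strsplit(tk, ".", fixed = TRUE)[[1]])
        idx <- seq(rng[1], rng[2]) + offset
      } else {
        idx <- as.integer(tk) + offset
      }
      if (any(idx < 1 | idx > cm$nchar)) {
        abort(paste0("ccode index out of range: ", tk))
      }
      switch(mode,
             "+" = { cm$ordered[idx] <- TRUE },
             "-" = { cm$ordered[idx] <- FALSE },
             "[" = { cm$active[idx] <- TRUE },
             "]" = { cm$active[idx] <- FALSE },
             "*" = { cm$ordered[idx] <- FALSE; cm$active[idx] <- TRUE
                     cm$weights[idx] <- 1 },
             "/" = { cm$weights[idx] <- weight })
    }
  }
  cm
}

parse_nexus_matrix <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)   # strip NEXUS comments
  get_num <- function(pat) {
    m <- regmatches(txt, regexpr(pat, txt, ignore.case = TRUE))
    if (length(m) == 0) abort(paste0("NEXUS: missing ", pat))
    as.integer(sub(".*=", "", m))
  }
  ntax <- get_num("NTAX\\s*=\\s*[0-9]+")
  nchar_ <- get_num("NCHAR\\s*=\\s*[0-9]+")
  mat <- regmatches(txt, regexpr("MATRIX(.|\n)*?;", txt, ignore.case = TRUE))
  if (length(mat) == 0) abort("NEXUS: no MATRIX block")
  body <- sub(";$", "", sub("^MATRIX", "", mat, ignore.case = TRUE))
  rows <- trimws(strsplit(body, "\n")[[1]])
  rows <- rows[rows != ""]
  taxa <- character(0)
  data <- list()
  for (rw in rows) {
    if (grepl("^'", rw)) {
      taxon <- sub("^'([^']*)'.*$", "\\1", rw)
      seqtxt <- trimws(sub("^'[^']*'", "", rw))
    } else {
      parts <- regmatches(rw, regexpr("^\\S+", rw))
      taxon <- parts
      seqtxt <- trimws(substr(rw, nchar(parts) + 1L, nchar(rw)))
    }
    toks <- tokenize_row(seqtxt, taxon)
    if (taxon %in% taxa) {
      data[[taxon]] <- c(data[[taxon]], toks)
    } else {
      taxa <- c(taxa, taxon)
      data[[taxon]] <- toks
    }
  }
  if (length(taxa) != ntax) {
    abort(paste0("NEXUS declares ", ntax, " taxa but ", length(taxa), " found"))
  }
  badlen <- taxa[vapply(data, length, 1L) != nchar_]
  if (length(badlen) > 0) {
    abort(paste0("row length != ", nchar_, " for taxon: ",
                 paste(badlen, collapse = ", ")))
  }
  cells <- do.call(rbind, data[taxa])
  cells[cells %in% c("?", "-")] <- NA_character_
  cm <- character_matrix(cells, taxa)
  # ASSUMPTIONS: TYPESET ... = ord: 1 3-5, unord: ...;  EXSET ... = 165 215;
  ts <- regmatches(txt, regexpr("TYPESET[^;]*;", txt, ignore.case = TRUE))
  if (length(ts) == 1) {
    ordpart <- regmatches(ts, regexpr("ord\\s*:[^,;]*", ts, ignore.case = TRUE))
    ordpart <- ordpart[!grepl("unord", ordpart, ignore.case = TRUE)]
    if (length(ordpart) == 1) {
      cm$ordered[parse_index_list(sub(".*:", "", ordpart))] <- TRUE
    }
  }
  ex <- regmatches(txt, regexpr("EXSET[^;]*;", txt, ignore.case = TRUE))
  if (length(ex) == 1) {
    cm$active[parse_index_list(sub(".*=", "", sub(";$", "", ex)))] <- FALSE
  }
  cm
}

# "1 3-5 7" -> c(1,3,4,5,7)
parse_index_list <- function(s) {
  toks <- regmatches(s, gregexpr("[0-9]+\\s*-\\s*[0-9]+|[0-9]+", s))[[1]]
  unlist(lapply(toks, function(tk) {
    if (grepl("-", tk)) {
      rng <- as.integer(strsplit(tk, "-")[[1]])
      seq(rng[1], rng[2])
    } else as.integer(tk)
  }))
}

#' Write a character matrix as TNT xread
#'
#' Emits the matrix plus a `ccode` line recording ordered and excluded
#' characters (0-based, the TNT convention).
#'
#' @param cm A `character_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tnt <- function(cm, path) {
  rows <- vapply(seq_len(cm$ntax), function(i) {
    toks <- cm$cells[i, ]
    toks[is.na(toks)] <- "?"
    toks <- ifelse(nchar(toks) > 1, paste0("[", toks, "]"), toks)
    paste0(gsub("\\s", "_", cm$taxa[i]), "\t", paste(toks, collapse = ""))
  }, character(1))
  out <- c(paste0("xread '", "synthetic matrix", "' ",
                  cm$nchar, " ", cm$ntax),
           rows, ";")
  cc <- character(0)
  if (any(cm$ordered)) {
    cc <- c(cc, paste("+", paste(which(cm$ordered) - 1L, collapse = " ")))
  }
  if (any(!cm$active)) {
    cc <- c(cc, paste("]", paste(which(!cm$active) - 1L, collapse = " ")))
  }
  if (length(cc) > 0) out <- c(out, paste0("ccode ", paste(cc, collapse = " "), ";"))
  out <- c(out, "proc /;")
  writeLines(out, path)
  invisible(path)
}
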