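# Delimiter sniffing: tab wins if present in the header line, else comma.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) stop("no data rows in ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

read_table_checked <- function(path, needed) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           na.strings = "", colClasses = "character")
  if (nrow(tab) == 0) stop("no data rows in ", path, call. = FALSE)
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop(path, " lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab
}

num_col <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop("non-numeric ", what, " in ", path, " at data row ", bad[1],
         " (\"", x[bad[1]], "\")", call. = FALSE)
  }
  out
}

#' Read a phase quantification table
#'
#' Reads a TSV (or CSV, sniffed from the header) with columns `phase`,
#' `formula`, `wtpct`, `esd`. Subscript markup in formulas
#' (`"Ca_5_(PO_4_)_3_OH"`) is normalised; formulas are parsed eagerly so
#' malformed input fails at read time with the offending row. A row whose
#' phase is `"Amorphous"` (any case, empty formula) is routed to the
#' assemblage's amorphous weight fraction.
#'
#' @param path file path.
#' @param label sample label; defaults to the file name.
#' @param closure_tol closure tolerance passed to [phase_assemblage()].
#' @return A [phase_assemblage()].
#' @export
read_phase_table <- function(path, label = basename(path),
                             closure_tol = 0.5) {
  tab <- read_table_checked(path, c("phase", "formula", "wtpct", "esd"))
  tab$wtpct <- num_col(tab$wtpct, "wtpct", path)
  tab$esd <- num_col(tab$esd, "esd", path)
  tab$esd[is.na(tab$esd)] <- 0
  is_am <- tolower(trimws(tab$phase)) == "amorphous"
  w_am <- 0; w_am_esd <- 0
  if (any(is_am)) {
    if (sum(is_am) > 1) stop("multiple amorphous rows in ", path,
                             call. = FALSE)
    w_am <- tab$wtpct[is_am]
    w_am_esd <- tab$esd[is_am]
  }
  cryst <- tab[!is_am, , drop = FALSE]
  cryst$formula <- vapply(cryst$formula, normalize_subscripts, character(1))
  bad <- which(is.na(cryst$wtpct))
  if (length(bad) > 0) stop("missing wtpct in ", path, " at data row ",
                            which(!is_am)[bad[1]], call. = FALSE)
  phase_assemblage(cryst[c("phase", "formula", "wtpct", "esd")],
                   amorphous_wtpct = w_am, amorphous_esd = w_am_esd,
                   label = label, closure_tol = closure_tol)
}

#' Read a bulk elemental analysis table
#'
#' Columns `element`, `value`, `sd`, `flag`. A value written `"<x"` is
#' auto-parsed as below detection with limit `x` (flag `"lt"`); flag
#' `"single"` marks a single measurement whose sd is treated as zero
#' downstream.
#'
#' @param path file path.
#' @param label sample label; defaults to the file name.
#' @return A [bulk_composition()].
#' @export
read_bulk_table <- function(path, label = basename(path)) {
  tab <- read_table_checked(path, c("element", "value", "sd", "flag"))
  tab$flag[is.na(tab$flag)] <- ""
  lt <- grepl("^\\s*<", tab$value)
  tab$value[lt] <- sub("^\\s*<\\s*", "", tab$value[lt])
  tab$flag[lt] <- "lt"
  tab$value <- num_col(tab$value, "value", path)
  tab$sd <- num_col(tab$sd, "sd", path)
  bulk_composition(tab[c("element", "value", "sd", "flag")], label = label)
}

#' Read a straw composition table
#'
#' Columns `element`, `value`, `sd`, `unit`, `flag`, plus one row with
#' element `"Ash"` carrying the ash content at 550 degrees C (% of dry
#' matter) that is routed to the `ash_content` attribute. `"<x"` values
#' are parsed as below detection.
#'
#' @param path file path.
#' @param label sample label; defaults to the file name.
#' @return A [straw_composition()].
#' @export
read_straw_table <- function(path, label = basename(path)) {
  tab <- read_table_checked(path, c("element", "value", "sd", "unit",
                                    "flag"))
  tab$flag[is.na(tab$flag)] <- ""
  lt <- grepl("^\\s*<", tab$value)
  tab$value[lt] <- sub("^\\s*<\\s*", "", tab$value[lt])
  tab$flag[lt] <- "lt"
  tab$value <- num_col(tab$value, "value", path)
  tab$sd <- num_col(tab$sd, "sd", path)
  tab$sd[is.na(tab$sd)] <- 0
  is_ash <- tab$element == "Ash"
  if (sum(is_ash) != 1) stop("straw table needs exactly one 'Ash' row: ",
                             path, call. = FALSE)
  straw_composition(tab[!is_ash, c("element", "value", "sd", "unit",
                                   "flag")],
                    ash_content = tab$value[is_ash],
                    ash_content_sd = tab$sd[is_ash], label = label)
}

#' Write a phase assemblage to TSV
#'
#' Inverse of [read_phase_table()]: crystalline rows plus an `Amorphous`
#' row with empty formula. Full numeric precision is kept so the
#' round-trip is the identity.
#'
#' @param assemblage a [phase_assemblage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phase_table <- function(assemblage, path) {
  stopifnot(inherits(assemblage, "phase_assemblage"))
  out <- data.frame(phase = assemblage$phase, formula = assemblage$formula,
                    wtpct = assemblage$wtpct, esd = assemblage$esd,
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(phase = "Amorphous", formula = "",
                               wtpct = attr(assemblage, "amorphous_wtpct"),
                               esd = attr(assemblage, "amorphous_esd")))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bulk composition to TSV
#'
#' Inverse of [read_bulk_table()]; below-detection rows are written back
#' as `"<limit"`.
#'
#' @param bulk a [bulk_composition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bulk_table <- function(bulk, path) {
  stopifnot(inherits(bulk, "bulk_composition"))
  value <- ifelse(bulk$flag == "lt", paste0("<", bulk$value),
                  as.character(bulk$value))
  out <- data.frame(element = bulk$element, value = value, sd = bulk$sd,
                    flag = ifelse(bulk$flag == "lt", "", bulk$flag),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
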