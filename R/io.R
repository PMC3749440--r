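TRACE_COLUMNS <- c("time_s", "trap_sep_nm", "defl1_nm", "defl2_nm",
                   "force_pN", "extension_nm", "state")

#' Write a trace to a tab-separated file
#'
#' Header columns `time_s, trap_sep_nm, defl1_nm, defl2_nm, force_pN,
#' extension_nm, state`; metadata (sample rate, seed, protocol) goes into
#' `#`-prefixed comment lines. Numbers are written with 9 significant
#' digits, enough for a lossless round trip at measurement precision.
#'
#' @param trace A `tweezer_trace` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(TRACE_COLUMNS %in% names(trace)))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sample_rate = attr(trace, "sample_rate"),
            seed = attr(trace, "seed"),
            protocol = attr(trace, "protocol"))
  for (nm in names(meta))
    if (!is.null(meta[[nm]]) && !is.na(meta[[nm]]))
      writeLines(sprintf("# %s=%s", nm, format(meta[[nm]], digits = 15)), con)
  df <- trace[, TRACE_COLUMNS]
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- signif(df[[cn]], 9)
  writeLines(paste(TRACE_COLUMNS, collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path File path.
#' @return A `tweezer_trace` with metadata attributes restored.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  all_lines <- readLines(path)
  hdr_line <- all_lines[!grepl("^#", all_lines)][1]
  hdr <- strsplit(hdr_line, "\t", fixed = TRUE)[[1]]
  missing <- setdiff(TRACE_COLUMNS, hdr)
  if (length(missing) > 0)
    stop("trace file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  classes <- ifelse(hdr == "state", "character", "numeric")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          na.strings = "NA", colClasses = classes)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("non-monotone time column", call. = FALSE)
  if (length(dt) > 1 && diff(range(dt)) > 1e-9 * max(dt) * length(dt))
    stop("sampling interval is not constant", call. = FALSE)
  if (!is.null(meta$sample_rate))
    attr(df, "sample_rate") <- as.numeric(meta$sample_rate)
  if (!is.null(meta$seed)) attr(df, "seed") <- as.integer(meta$seed)
  if (!is.null(meta$protocol)) attr(df, "protocol") <- meta$protocol
  class(df) <- c("tweezer_trace", "data.frame")
  df
}

#' Read a key=value run configuration
#'
#' Plain-text configuration with one `key=value` per line (`#` comments
#' allowed). Known keys mirror the [assay_config()] fields plus tether
#' element definitions `tether<i>.kind/L/p/K/n_segments` and hairpin
#' fields `hairpin.released_nt/nm_per_nt/folded_width/ssdna_p/dG0`; a
#' `preset` key loads a [preset_config()] and applies overrides. Unknown
#' keys are rejected.
#'
#' @param path File path.
#' @return An [assay_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  names(vals) <- keys
  vals <- as.list(vals)
  scalar_keys <- c("pulling_speed", "mc_rate", "output_rate", "step_size",
                   "seed", "kT", "trap1.k_perp", "trap1.k_beam",
                   "trap2.k_perp", "trap2.k_beam")
  known <- function(k)
    k %in% c("preset", scalar_keys) ||
      grepl("^tether[0-9]+\\.(kind|L|p|K|n_segments)$", k) ||
      grepl("^hairpin\\.(released_nt|nm_per_nt|folded_width|ssdna_p|dG0)$", k)
  if (any(!vapply(keys, known, logical(1))))
    stop("unknown config key(s): ",
         paste(keys[!vapply(keys, known, logical(1))], collapse = ", "),
         call. = FALSE)
  if ("preset" %in% keys) {
    cfg <- preset_config(vals[["preset"]])
  } else {
    idx <- sort(unique(as.integer(sub("^tether([0-9]+)\\..*$", "\\1",
                                      grep("^tether", keys, value = TRUE)))))
    if (length(idx) == 0)
      stop("config defines no tether elements and no preset", call. = FALSE)
    tether <- lapply(idx, function(i) {
      g <- function(f) vals[[sprintf("tether%d.%s", i, f)]]
      polymer_model(g("kind"),
                    L = if (!is.null(g("L"))) as.numeric(g("L")),
                    p = if (!is.null(g("p"))) as.numeric(g("p")),
                    K = if (!is.null(g("K"))) as.numeric(g("K")),
                    n_segments = if (!is.null(g("n_segments")))
                      as.integer(g("n_segments")))
    })
    hp <- NULL
    if ("hairpin.released_nt" %in% keys) {
      g <- function(f, d) if (!is.null(vals[[paste0("hairpin.", f)]]))
        as.numeric(vals[[paste0("hairpin.", f)]]) else d
      hp <- hairpin_model(g("released_nt", NULL), g("nm_per_nt", 0.59),
                          g("folded_width", 2.0), g("ssdna_p", 1.0),
                          g("dG0", 0))
    }
    cfg <- assay_config(tether, hairpin = hp)
  }
  num <- function(k, cur) if (k %in% keys) as.numeric(vals[[k]]) else cur
  cfg$pulling_speed <- num("pulling_speed", cfg$pulling_speed)
  cfg$mc_rate <- num("mc_rate", cfg$mc_rate)
  cfg$output_rate <- num("output_rate", cfg$output_rate)
  cfg$step_size <- num("step_size", cfg$step_size)
  if ("seed" %in% keys) cfg$seed <- as.integer(vals[["seed"]])
  if ("kT" %in% keys) cfg$thermal <- thermal(as.numeric(vals[["kT"]]))
  cfg$trap1 <- trap_model(num("trap1.k_perp", cfg$trap1$k_perp),
                          num("trap1.k_beam", cfg$trap1$k_beam))
  cfg$trap2 <- trap_model(num("trap2.k_perp", cfg$trap2$k_perp),
                          num("trap2.k_beam", cfg$trap2$k_beam))
  if (cfg$mc_rate %% cfg$output_rate != 0)
    stop("mc_rate must be an integer multiple of output_rate", call. = FALSE)
  cfg
}

#' Write / read polyline ensembles as TSV
#'
#' Two columns (`x_nm`, `y_nm`), one chain per block, blank lines between
#' chains.
#'
#' @param chains List of `n x 2` matrices.
#' @param path File path.
#' @return `path` (write) or a list of matrices (read).
#' @export
write_chains <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("x_nm\ty_nm", con)
  for (xy in chains) {
    utils::write.table(signif(xy, 9), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_chains
#' @export
read_chains <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) > 0 && grepl("^x_nm", lines[1])) lines <- lines[-1]
  blocks <- split(lines, cumsum(!nzchar(lines)))
  out <- lapply(blocks, function(b) {
    b <- b[nzchar(b)]
    if (length(b) == 0) return(NULL)
    do.call(rbind, lapply(strsplit(b, "\t"), as.numeric))
  })
  out[!vapply(out, is.null, logical(1))]
}
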