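# Minimal WFDB support: .hea headers, signal formats 16 (16-bit little-endian)
# and 212 (packed 12-bit pairs), and MIT-format .atr beat annotations. Covers
# what single-lead extraction from the public arrhythmia databases needs; no
# multi-segment records, no skew/offset fields.

# annotation code -> symbol (subset of the standard code table)
.wfdb_codes <- c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/",
                 "Q", "~", "", "|", "", "s", "T", "*", "D", "\"", "=", "p",
                 "B", "^", "t", "+", "u", "?", "!", "[", "]", "e", "n", "@",
                 "x", "f", "(", ")")
.wfdb_beat_codes <- c(1:13, 25, 34, 35, 38)  # codes that mark beats

#' Read a WFDB record
#'
#' Parses `<prefix>.hea`, loads one channel from `<prefix>.dat` (formats 16
#' and 212), converts to physical units via gain and baseline, and maps
#' `<prefix>.atr` beat annotations (when present) onto `beat_labels`.
#' Non-beat annotations are ignored; beat codes outside the symbol table are
#' recorded as `"Q"` (unknown) with a warning.
#'
#' @param prefix Record path prefix, with or without `.hea`.
#' @param channel 1-based signal channel to extract.
#' @return An [ecg_record()] at the record's native sampling rate.
#' @export
read_wfdb <- function(prefix, channel = 1L) {
  prefix <- sub("\\.hea$", "", prefix)
  hea <- paste0(prefix, ".hea")
  if (!file.exists(hea)) stop("cannot read file: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rl <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rl[2])
  fs <- if (length(rl) >= 3) as.numeric(sub("/.*$", "", rl[3])) else 250
  nsamp <- if (length(rl) >= 4) as.integer(rl[4]) else NA_integer_
  if (channel > nsig) stop("record has only ", nsig, " signals")
  sig <- lapply(lines[2:(1 + nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain_spec <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("^([-0-9.eE+]+).*", "\\1", gain_spec))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec)) else NA
    adczero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    list(file = f[1], format = as.integer(sub("x.*|:.*|\\+.*", "", f[2])),
         gain = gain,
         baseline = if (is.na(baseline)) adczero else baseline,
         desc = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
                else paste0("ch", which(lines == l)))
  })
  datfile <- file.path(dirname(hea), sig[[channel]]$file)
  fmt <- sig[[channel]]$format
  raw <- readBin(datfile, "raw", n = file.info(datfile)$size)
  adc <- switch(as.character(fmt),
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                   signed = TRUE, endian = "little")
      matrix(v, ncol = nsig, byrow = TRUE)
    },
    "212" = decode_fmt212(raw, nsig),
    stop("unsupported WFDB signal format: ", fmt))
  if (!is.na(nsamp) && nrow(adc) > nsamp) adc <- adc[seq_len(nsamp), , drop = FALSE]
  x <- (adc[, channel] - sig[[channel]]$baseline) / sig[[channel]]$gain
  beats <- NULL
  atr <- paste0(prefix, ".atr")
  if (file.exists(atr)) {
    ann <- read_wfdb_annotations(atr)
    ann <- ann[ann$code %in% .wfdb_beat_codes, , drop = FALSE]
    if (nrow(ann)) {
      sym <- ifelse(ann$code <= length(.wfdb_codes) &
                      nzchar(.wfdb_codes[ann$code]),
                    .wfdb_codes[ann$code], NA)
      if (anyNA(sym)) {
        warning("unknown annotation code(s) recorded as 'Q'")
        sym[is.na(sym)] <- "Q"
      }
      keep <- ann$time < length(x)
      beats <- data.frame(index = ann$time[keep], cls = sym[keep])
      beats <- beats[!duplicated(beats$index), , drop = FALSE]
    }
  }
  desc <- sig[[channel]]$desc
  ecg_record(x, fs = fs, lead = desc, beat_labels = beats)
}

decode_fmt212 <- function(raw, nsig) {
  n3 <- (length(raw) %/% 3) * 3
  b <- as.integer(raw[seq_len(n3)])
  b1 <- b[seq(1, n3, 3)]; b2 <- b[seq(2, n3, 3)]; b3 <- b[seq(3, n3, 3)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0F), 8)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4), 8)
  s1 <- ifelse(s1 > 2047, s1 - 4096, s1)  # 12-bit two's complement
  s2 <- ifelse(s2 > 2047, s2 - 4096, s2)
  v <- as.vector(rbind(s1, s2))
  n <- (length(v) %/% nsig) * nsig
  matrix(v[seq_len(n)], ncol = nsig, byrow = TRUE)
}

read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  b <- as.integer(raw)
  i <- 1L; t_cur <- 0L
  times <- integer(0); codes <- integer(0)
  while (i + 1L <= length(b)) {
    a <- b[i] + bitwShiftL(b[i + 1L], 8)
    code <- bitwShiftR(a, 10)
    dt <- bitwAnd(a, 1023L)
    i <- i + 2L
    if (code == 0L && dt == 0L) break          # EOF
    if (code == 59L) {                          # SKIP: 4-byte interval follows
      hi <- b[i] + bitwShiftL(b[i + 1L], 8)
      lo <- b[i + 2L] + bitwShiftL(b[i + 3L], 8)
      i <- i + 4L
      t_cur <- t_cur + bitwShiftL(hi, 16) + lo
    } else if (code == 63L) {                   # AUX: skip payload
      i <- i + dt + (dt %% 2L)
    } else if (code %in% c(60L, 61L, 62L)) {    # NUM/SUB/CHN: no time advance
    } else {
      t_cur <- t_cur + dt
      times <- c(times, t_cur)
      codes <- c(codes, code)
    }
  }
  data.frame(time = times, code = codes)
}

#' Write a WFDB record (format 16)
#'
#' Writes `<prefix>.hea`, `<prefix>.dat` (single signal, format 16, gain 200
#' adu/mV) and, when beats are present, `<prefix>.atr`. Mainly used to build
#' test fixtures and to exchange synthetic records with WFDB-based tools.
#'
#' @param rec An [ecg_record()].
#' @param prefix Output path prefix.
#' @param gain ADC units per mV.
#' @return `prefix`, invisibly.
#' @export
write_wfdb <- function(rec, prefix, gain = 200) {
  name <- basename(prefix)
  n <- length(rec$samples)
  adc <- as.integer(round(rec$samples * gain))
  adc <- pmax(pmin(adc, 32767L), -32768L)
  writeLines(c(sprintf("%s 1 %g %d", name, rec$fs, n),
               sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
                       name, gain, adc[1], rec$lead)),
             paste0(prefix, ".hea"))
  writeBin(adc, paste0(prefix, ".dat"), size = 2, endian = "little")
  beats <- rec$beat_labels
  if (!is.null(beats) && nrow(beats)) {
    sym2code <- c(N = 1L, L = 2L, R = 3L, a = 4L, V = 5L, F = 6L, J = 7L,
                  A = 8L, S = 9L, E = 10L, j = 11L, `/` = 12L, Q = 13L,
                  e = 34L, n = 35L, f = 38L)
    out <- raw(0)
    t_prev <- 0L
    pair <- function(code, dt) {
      a <- bitwOr(bitwShiftL(code, 10), dt)
      as.raw(c(bitwAnd(a, 255L), bitwShiftR(a, 8)))
    }
    for (k in seq_len(nrow(beats))) {
      code <- sym2code[[beats$cls[k]]]
      if (is.null(code)) code <- 13L
      dt <- beats$index[k] - t_prev
      if (dt > 1023L) {
        out <- c(out, pair(59L, 0L),
                 as.raw(c(bitwAnd(bitwShiftR(dt, 16), 255L),
                          bitwAnd(bitwShiftR(dt, 24), 255L),
                          bitwAnd(dt, 255L),
                          bitwAnd(bitwShiftR(dt, 8), 255L))))
        dt <- 0L
      }
      out <- c(out, pair(code, dt))
      t_prev <- beats$index[k]
    }
    out <- c(out, as.raw(c(0, 0)))
    writeBin(out, paste0(prefix, ".atr"))
  }
  invisible(prefix)
}
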