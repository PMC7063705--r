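Package: psytimex
Title: Time Expression Extraction and Normalization for Mental-Health Clinical Text
Version: 0.1.0
Authors@R:
    person("psytimex", "developers", email = "psytimex@example.org", role = c("aut", "cre"))
Description: Rule-based extraction and normalization of time expressions in
    long mental-health clinical narratives, designed to support duration of
    untreated psychosis (DUP) research. Detects five expression types (Date,
    Time, Duration, Frequency and Age_related), normalizes them to a
    TIMEX-style value grammar extended with bounded intervals (SIN/UNT),
    ranges, age values and categorical life-stage references, anchors
    relative expressions to a document creation time, triages large document
    collections with a four-stage filter (length, average line length,
    psychosis symptom keywords, time-expression count), and scores system
    output or annotator pairs with lenient span F1 and value accuracy
    (raw and clock-relaxed). Includes a deterministic synthetic-corpus
    generator with gold annotations, brat-style standoff I/O and a TIMEX3
    XML reader.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
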