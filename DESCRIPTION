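Package: revnano
Title: Reverse Engineering DNA Origami Designs from Scaffold and Staple Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers the staple-scaffold contact map of a scaffolded DNA (or
    RNA, or hybrid) origami nanostructure from nothing but the raw scaffold
    sequence and the 5'->3' staple sequence list, using a constraint-programming
    solver built on staple routing trees, footprint propagation and
    clearest-shortest-path placement.  The recovered contact map is converted to
    a typed domain-level graph and embedded in 2D or 3D by Kamada-Kawai stress
    minimisation to produce an interactive HTML guide schematic, with junction
    sequence-ambiguity annotation.  A forward-design generator produces raster
    origami fixtures with known ground-truth contact maps, plus input-noise
    models, so the whole pipeline is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
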