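Package: treepatterns
Title: Pattern Occurrences in Random Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact enumeration and Monte-Carlo exploration of fixed-pattern
    occurrences (such as the snowflake) in random phylogenetic trees.
    Provides exact big-integer counting of binary phylogenetic trees, forests
    and snowflake central vertices with their closed-form densities;
    exactly-uniform samplers for leaf-labelled d-ary trees via size-conditioned
    critical Galton-Watson trees and the cycle lemma; Yule-Harding and
    truncated Kesten-tree (local limit) samplers; a degree-exact pattern
    embedding engine with an exhaustive oracle; and seeded experiments that
    exhibit the 0-1 law for pattern occurrence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
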