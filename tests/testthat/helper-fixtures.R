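# Frozen expected values and small programmatic fixtures.

# The 28 pairs printed for the 8-heading worked-example citation
# (PMID 20464912), in their printed orientation.
table5_pairs <- function() {
  txt <- c(
    "physiopathology|rehabilitation",
    "physiopathology|Evidence-Based Medicine",
    "physiopathology|Humans",
    "physiopathology|Muscle Stretching Exercises",
    "physiopathology|Physical Fitness",
    "physiopathology|Resistance Training",
    "physiopathology|Treatment Outcome",
    "rehabilitation|Evidence-Based Medicine",
    "rehabilitation|Humans",
    "rehabilitation|Muscle Stretching Exercises",
    "rehabilitation|Physical Fitness",
    "rehabilitation|Resistance Training",
    "rehabilitation|Treatment Outcome",
    "Evidence-Based Medicine|Humans",
    "Evidence-Based Medicine|Muscle Stretching Exercises",
    "Evidence-Based Medicine|Physical Fitness",
    "Evidence-Based Medicine|Resistance Training",
    "Evidence-Based Medicine|Treatment Outcome",
    "Humans|Muscle Stretching Exercises",
    "Humans|Physical Fitness",
    "Humans|Resistance Training",
    "Humans|Treatment Outcome",
    "Muscle Stretching Exercises|Physical Fitness",
    "Muscle Stretching Exercises|Resistance Training",
    "Muscle Stretching Exercises|Treatment Outcome",
    "Physical Fitness|Resistance Training",
    "Physical Fitness|Treatment Outcome",
    "Resistance Training|Treatment Outcome")
  parts <- strsplit(txt, "|", fixed = TRUE)
  data.frame(a = vapply(parts, `[`, character(1), 1),
    b = vapply(parts, `[`, character(1), 2),
    stringsAsFactors = FALSE)
}

# small MEDLINE-dialect citation XML written in code
write_medline_fixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<PubmedArticleSet>",
    "  <PubmedArticle><MedlineCitation>",
    "    <PMID>100</PMID>",
    "    <MeshHeadingList>",
    "      <MeshHeading>",
    '        <DescriptorName MajorTopicYN="Y">Arthritis, Rheumatoid</DescriptorName>',
    '        <QualifierName MajorTopicYN="N">drug therapy</QualifierName>',
    "      </MeshHeading>",
    "      <MeshHeading>",
    '        <DescriptorName MajorTopicYN="N">Humans</DescriptorName>',
    "      </MeshHeading>",
    "      <MeshHeading>",
    '        <DescriptorName MajorTopicYN="N">Inflammation</DescriptorName>',
    '        <QualifierName MajorTopicYN="Y">immunology</QualifierName>',
    "      </MeshHeading>",
    "    </MeshHeadingList>",
    "  </MedlineCitation></PubmedArticle>",
    "  <PubmedArticle><MedlineCitation>",
    "    <PMID>101</PMID>",
    "    <MeshHeadingList>",
    "      <MeshHeading>",
    '        <DescriptorName MajorTopicYN="N">Apoptosis</DescriptorName>',
    "      </MeshHeading>",
    "    </MeshHeadingList>",
    "  </MedlineCitation></PubmedArticle>",
    "  <PubmedArticle><MedlineCitation>",
    "    <PMID>102</PMID>",
    "    <MeshHeadingList/>",
    "  </MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"), path)
  path
}

# two planted stars sharing five rim nodes, built edge by edge
two_star_frame <- function(shared = 5, extraA = 3, extraB = 2,
                           with_hub_edge = FALSE) {
  sh <- sprintf("S%02d", seq_len(shared))
  ea <- sprintf("A%02d", seq_len(extraA))
  eb <- sprintf("B%02d", seq_len(extraB))
  df <- rbind(
    data.frame(a = "HubA", b = c(sh, ea), frequency = 14L),
    data.frame(a = "HubB", b = c(sh, eb), frequency = 14L))
  if (with_hub_edge)
    df <- rbind(df, data.frame(a = "HubA", b = "HubB", frequency = 14L))
  df
}
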