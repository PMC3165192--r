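<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <PMID>19264955</PMID>
    <ArticleTitle>Example abstract 1</ArticleTitle>
    <AbstractText>Fisetin induces apoptosis in HCT-116 cells.</AbstractText>
  </PubmedArticle>
  <PubmedArticle>
    <PMID>19262372</PMID>
    <ArticleTitle>Example abstract 2</ArticleTitle>
    <AbstractText>Docetaxel was a more potent inducer of apoptosis.</AbstractText>
  </PubmedArticle>
  <PubmedArticle>
    <PMID>18070986</PMID>
    <ArticleTitle>Example abstract 3</ArticleTitle>
    <AbstractText>Wogonin induces apoptosis in malignant T cells.</AbstractText>
  </PubmedArticle>
  <PubmedArticle>
    <PMID>19258429</PMID>
    <ArticleTitle>Example abstract 4</ArticleTitle>
    <AbstractText>Tolfenamic acid induces Sp protein degradation in several cancer cell lines.</AbstractText>
  </PubmedArticle>
</PubmedArticleSet>
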