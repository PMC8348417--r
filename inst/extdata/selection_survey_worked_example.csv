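subject,measure,electrode,channel,adopted
1,PEE,1,AF3,1
1,PEE,2,AF4,0
1,PEE,3,FT7,1
1,PEE,4,FT8,1
1,PEE,5,T7,1
1,PEE,6,T8,1
1,PEE,7,TP7,1
1,PEE,8,TP8,1
1,SVE,1,AF3,0
1,SVE,2,AF4,0
1,SVE,3,FT7,0
1,SVE,4,FT8,0
1,SVE,5,T7,0
1,SVE,6,T8,1
1,SVE,7,TP7,1
1,SVE,8,TP8,0
1,APE,1,AF3,0
1,APE,2,AF4,1
1,APE,3,FT7,0
1,APE,4,FT8,1
1,APE,5,T7,1
1,APE,6,T8,1
1,APE,7,TP7,0
1,APE,8,TP8,1
1,SAE,1,AF3,0
1,SAE,2,AF4,0
1,SAE,3,FT7,0
1,SAE,4,FT8,1
1,SAE,5,T7,1
1,SAE,6,T8,1
1,SAE,7,TP7,1
1,SAE,8,TP8,1
1,SPE,1,AF3,1
1,SPE,2,AF4,1
1,SPE,3,FT7,1
1,SPE,4,FT8,0
1,SPE,5,T7,0
1,SPE,6,T8,1
1,SPE,7,TP7,1
1,SPE,8,TP8,0
1,CWE,1,AF3,1
1,CWE,2,AF4,1
1,CWE,3,FT7,0
1,CWE,4,FT8,0
1,CWE,5,T7,0
1,CWE,6,T8,1
1,CWE,7,TP7,1
1,CWE,8,TP8,0
2,PEE,1,AF3,0
2,PEE,2,AF4,1
2,PEE,3,FT7,0
2,PEE,4,FT8,0
2,PEE,5,T7,1
2,PEE,6,T8,0
2,PEE,7,TP7,0
2,PEE,8,TP8,0
2,SVE,1,AF3,1
2,SVE,2,AF4,0
2,SVE,3,FT7,1
2,SVE,4,FT8,1
2,SVE,5,T7,1
2,SVE,6,T8,0
2,SVE,7,TP7,0
2,SVE,8,TP8,1
2,APE,1,AF3,0
2,APE,2,AF4,1
2,APE,3,FT7,0
2,APE,4,FT8,1
2,APE,5,T7,1
2,APE,6,T8,0
2,APE,7,TP7,0
2,APE,8,TP8,1
2,SAE,1,AF3,0
2,SAE,2,AF4,1
2,SAE,3,FT7,0
2,SAE,4,FT8,1
2,SAE,5,T7,0
2,SAE,6,T8,1
2,SAE,7,TP7,0
2,SAE,8,TP8,1
2,SPE,1,AF3,0
2,SPE,2,AF4,1
2,SPE,3,FT7,0
2,SPE,4,FT8,1
2,SPE,5,T7,1
2,SPE,6,T8,1
2,SPE,7,TP7,0
2,SPE,8,TP8,1
2,CWE,1,AF3,1
2,CWE,2,AF4,1
2,CWE,3,FT7,0
2,CWE,4,FT8,1
2,CWE,5,T7,1
2,CWE,6,T8,1
2,CWE,7,TP7,0
2,CWE,8,TP8,0
3,PEE,1,AF3,0
3,PEE,2,AF4,0
3,PEE,3,FT7,0
3,PEE,4,FT8,1
3,PEE,5,T7,0
3,PEE,6,T8,0
3,PEE,7,TP7,0
3,PEE,8,TP8,1
3,SVE,1,AF3,1
3,SVE,2,AF4,1
3,SVE,3,FT7,1
3,SVE,4,FT8,1
3,SVE,5,T7,1
3,SVE,6,T8,1
3,SVE,7,TP7,1
3,SVE,8,TP8,1
3,APE,1,AF3,0
3,APE,2,AF4,0
3,APE,3,FT7,1
3,APE,4,FT8,1
3,APE,5,T7,0
3,APE,6,T8,1
3,APE,7,TP7,0
3,APE,8,TP8,0
3,SAE,1,AF3,1
3,SAE,2,AF4,1
3,SAE,3,FT7,1
3,SAE,4,FT8,1
3,SAE,5,T7,0
3,SAE,6,T8,1
3,SAE,7,TP7,1
3,SAE,8,TP8,1
3,SPE,1,AF3,1
3,SPE,2,AF4,1
3,SPE,3,FT7,1
3,SPE,4,FT8,1
3,SPE,5,T7,0
3,SPE,6,T8,0
3,SPE,7,TP7,1
3,SPE,8,TP8,1
3,CWE,1,AF3,0
3,CWE,2,AF4,1
3,CWE,3,FT7,0
3,CWE,4,FT8,1
3,CWE,5,T7,0
3,CWE,6,T8,1
3,CWE,7,TP7,1
3,CWE,8,TP8,0
4,PEE,1,AF3,0
4,PEE,2,AF4,0
4,PEE,3,FT7,0
4,PEE,4,FT8,0
4,PEE,5,T7,0
4,PEE,6,T8,1
4,PEE,7,TP7,1
4,PEE,8,TP8,0
4,SVE,1,AF3,1
4,SVE,2,AF4,0
4,SVE,3,FT7,0
4,SVE,4,FT8,0
4,SVE,5,T7,0
4,SVE,6,T8,1
4,SVE,7,TP7,0
4,SVE,8,TP8,0
4,APE,1,AF3,0
4,APE,2,AF4,0
4,APE,3,FT7,0
4,APE,4,FT8,1
4,APE,5,T7,0
4,APE,6,T8,1
4,APE,7,TP7,0
4,APE,8,TP8,0
4,SAE,1,AF3,1
4,SAE,2,AF4,0
4,SAE,3,FT7,0
4,SAE,4,FT8,0
4,SAE,5,T7,0
4,SAE,6,T8,0
4,SAE,7,TP7,1
4,SAE,8,TP8,0
4,SPE,1,AF3,1
4,SPE,2,AF4,0
4,SPE,3,FT7,1
4,SPE,4,FT8,0
4,SPE,5,T7,0
4,SPE,6,T8,1
4,SPE,7,TP7,0
4,SPE,8,TP8,0
4,CWE,1,AF3,1
4,CWE,2,AF4,1
4,CWE,3,FT7,0
4,CWE,4,FT8,0
4,CWE,5,T7,0
4,CWE,6,T8,1
4,CWE,7,TP7,0
4,CWE,8,TP8,0
5,PEE,1,AF3,1
5,PEE,2,AF4,0
5,PEE,3,FT7,1
5,PEE,4,FT8,1
5,PEE,5,T7,1
5,PEE,6,T8,1
5,PEE,7,TP7,1
5,PEE,8,TP8,1
5,SVE,1,AF3,0
5,SVE,2,AF4,1
5,SVE,3,FT7,0
5,SVE,4,FT8,1
5,SVE,5,T7,0
5,SVE,6,T8,1
5,SVE,7,TP7,0
5,SVE,8,TP8,0
5,APE,1,AF3,0
5,APE,2,AF4,1
5,APE,3,FT7,0
5,APE,4,FT8,1
5,APE,5,T7,0
5,APE,6,T8,1
5,APE,7,TP7,1
5,APE,8,TP8,0
5,SAE,1,AF3,0
5,SAE,2,AF4,1
5,SAE,3,FT7,1
5,SAE,4,FT8,1
5,SAE,5,T7,0
5,SAE,6,T8,1
5,SAE,7,TP7,1
5,SAE,8,TP8,0
5,SPE,1,AF3,1
5,SPE,2,AF4,1
5,SPE,3,FT7,0
5,SPE,4,FT8,0
5,SPE,5,T7,1
5,SPE,6,T8,0
5,SPE,7,TP7,0
5,SPE,8,TP8,0
5,CWE,1,AF3,0
5,CWE,2,AF4,0
5,CWE,3,FT7,0
5,CWE,4,FT8,0
5,CWE,5,T7,0
5,CWE,6,T8,1
5,CWE,7,TP7,0
5,CWE,8,TP8,1
6,PEE,1,AF3,0
6,PEE,2,AF4,0
6,PEE,3,FT7,0
6,PEE,4,FT8,0
6,PEE,5,T7,1
6,PEE,6,T8,1
6,PEE,7,TP7,1
6,PEE,8,TP8,0
6,SVE,1,AF3,1
6,SVE,2,AF4,1
6,SVE,3,FT7,0
6,SVE,4,FT8,1
6,SVE,5,T7,1
6,SVE,6,T8,1
6,SVE,7,TP7,1
6,SVE,8,TP8,1
6,APE,1,AF3,0
6,APE,2,AF4,0
6,APE,3,FT7,0
6,APE,4,FT8,1
6,APE,5,T7,0
6,APE,6,T8,1
6,APE,7,TP7,0
6,APE,8,TP8,0
6,SAE,1,AF3,1
6,SAE,2,AF4,1
6,SAE,3,FT7,0
6,SAE,4,FT8,1
6,SAE,5,T7,1
6,SAE,6,T8,1
6,SAE,7,TP7,1
6,SAE,8,TP8,1
6,SPE,1,AF3,1
6,SPE,2,AF4,1
6,SPE,3,FT7,0
6,SPE,4,FT8,0
6,SPE,5,T7,1
6,SPE,6,T8,1
6,SPE,7,TP7,1
6,SPE,8,TP8,1
6,CWE,1,AF3,1
6,CWE,2,AF4,0
6,CWE,3,FT7,1
6,CWE,4,FT8,0
6,CWE,5,T7,0
6,CWE,6,T8,1
6,CWE,7,TP7,0
6,CWE,8,TP8,1
7,PEE,1,AF3,0
7,PEE,2,AF4,0
7,PEE,3,FT7,0
7,PEE,4,FT8,1
7,PEE,5,T7,0
7,PEE,6,T8,0
7,PEE,7,TP7,0
7,PEE,8,TP8,1
7,SVE,1,AF3,1
7,SVE,2,AF4,1
7,SVE,3,FT7,0
7,SVE,4,FT8,1
7,SVE,5,T7,1
7,SVE,6,T8,1
7,SVE,7,TP7,1
7,SVE,8,TP8,1
7,APE,1,AF3,0
7,APE,2,AF4,0
7,APE,3,FT7,0
7,APE,4,FT8,0
7,APE,5,T7,0
7,APE,6,T8,0
7,APE,7,TP7,1
7,APE,8,TP8,1
7,SAE,1,AF3,0
7,SAE,2,AF4,0
7,SAE,3,FT7,1
7,SAE,4,FT8,1
7,SAE,5,T7,0
7,SAE,6,T8,0
7,SAE,7,TP7,1
7,SAE,8,TP8,1
7,SPE,1,AF3,0
7,SPE,2,AF4,0
7,SPE,3,FT7,0
7,SPE,4,FT8,0
7,SPE,5,T7,0
7,SPE,6,T8,0
7,SPE,7,TP7,1
7,SPE,8,TP8,1
7,CWE,1,AF3,1
7,CWE,2,AF4,0
7,CWE,3,FT7,0
7,CWE,4,FT8,1
7,CWE,5,T7,0
7,CWE,6,T8,1
7,CWE,7,TP7,0
7,CWE,8,TP8,0
8,PEE,1,AF3,0
8,PEE,2,AF4,1
8,PEE,3,FT7,0
8,PEE,4,FT8,0
8,PEE,5,T7,1
8,PEE,6,T8,1
8,PEE,7,TP7,0
8,PEE,8,TP8,0
8,SVE,1,AF3,1
8,SVE,2,AF4,0
8,SVE,3,FT7,1
8,SVE,4,FT8,0
8,SVE,5,T7,0
8,SVE,6,T8,0
8,SVE,7,TP7,1
8,SVE,8,TP8,0
8,APE,1,AF3,1
8,APE,2,AF4,0
8,APE,3,FT7,0
8,APE,4,FT8,0
8,APE,5,T7,0
8,APE,6,T8,0
8,APE,7,TP7,1
8,APE,8,TP8,0
8,SAE,1,AF3,1
8,SAE,2,AF4,1
8,SAE,3,FT7,0
8,SAE,4,FT8,0
8,SAE,5,T7,0
8,SAE,6,T8,0
8,SAE,7,TP7,1
8,SAE,8,TP8,1
8,SPE,1,AF3,1
8,SPE,2,AF4,0
8,SPE,3,FT7,0
8,SPE,4,FT8,0
8,SPE,5,T7,0
8,SPE,6,T8,0
8,SPE,7,TP7,1
8,SPE,8,TP8,0
8,CWE,1,AF3,1
8,CWE,2,AF4,1
8,CWE,3,FT7,0
8,CWE,4,FT8,0
8,CWE,5,T7,1
8,CWE,6,T8,0
8,CWE,7,TP7,0
8,CWE,8,TP8,0
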