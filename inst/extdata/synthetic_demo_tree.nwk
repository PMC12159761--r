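(((ASV_0058:2.21099185,(((((ASV_0008:3.838550528,ASV_0036:0.597520615):0.06148815621,(ASV_0004:0.2379030939,ASV_0022:0.429707387):2.453601202):0.8237599048,((ASV_0018:0.1421295605,ASV_0045:0.09447306699):1.468138354,(ASV_0028:1.040001341,((ASV_0005:0.94815729,ASV_0057:3.369137615):1.30827844,ASV_0034:1.885148054):0.9702436411):0.7872366558):2.295044708):0.7968274393,((((ASV_0035:0.9541903678,(ASV_0024:1.022931143,(ASV_0023:0.514111205,ASV_0026:0.2059369944):2.51588908):1.238963228):3.972916963,((ASV_0006:0.735003282,ASV_0054:0.2718373917):2.813148193,ASV_0002:1.65706856):1.549494142):1.051087515,ASV_0003:0.9729375848):3.66173025,(((ASV_0021:1.592052611,ASV_0043:0.3064364977):2.568636292,(ASV_0038:1.26825487,ASV_0010:1.521565525):0.2982842591):2.423868752,((ASV_0052:0.2484240501,ASV_0033:0.4448184287):0.1296444451,ASV_0009:0.5014719786):0.8123739659):0.9210096616):0.118525666):0.09924082691,((ASV_0029:0.3506391547,(ASV_0012:0.6295151804,ASV_0020:0.8620252655):0.9128402885):1.290238986,(ASV_0049:2.534134464,(((ASV_0011:3.087351598,ASV_0042:0.2587804313):3.068191178,ASV_0016:0.3050375862):1.132288179,(ASV_0037:1.703313516,(ASV_0048:1.168314097,(ASV_0014:0.4038126002,ASV_0027:0.1995707179):0.886932763):0.4797815518):2.258126264):0.597193276):1.329675546):0.001648378034):2.077429872):0.122875913,((((ASV_0056:0.4205557052,ASV_0040:0.07519860498):2.750048416,(ASV_0055:0.8873147762,ASV_0017:0.1994317099):3.175444309):0.5165402251,ASV_0041:0.6371392258):0.9812827967,((((ASV_0046:0.3820977492,ASV_0025:2.289027134):1.726456614,ASV_0059:3.918536624):0.3637571262,ASV_0007:0.02647905564):0.05966847008,(ASV_0053:1.368233678,(ASV_0019:0.7530137058,ASV_0051:2.427881913):0.0748509352):0.2614523033):2.644758029):2.531216977):2.161630647,(((((ASV_0031:0.7347695155,(ASV_0060:0.08582563419,ASV_0015:2.237314934):1.255647753):0.5557725201,((ASV_0047:0.02984603122,ASV_0032:0.09102870803):0.02831474412,ASV_0050:0.7512917212):0.9287518207):0.7300378615,(ASV_0013:1.349516778,ASV_0001:1.455359953):3.518419822):1.609004524,(ASV_0030:0.2513364203,ASV_0039:0.8967717867):0.3002573429):2.180591602,ASV_0044:0.7920805385):1.236775883);
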